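#' Structural roles of taxa from a module partition
#'
#' Characterises every node by (i) its standardised within-module degree
#' `z = (k_is - mean_s) / sd_s`, where `k_is` counts the node's links into
#' its own module and the mean/SD are taken over that module's nodes of the
#' same guild (insects are standardised against insects, hosts against
#' hosts), and (ii) its among-module connectivity
#' `c = 1 - sum_t (k_it / k_i)^2` over modules `t`.  Nodes are classified
#' with the conventional thresholds for plant-animal networks:
#' `z >= z_hub` marks a hub, `c > c_connector` marks a connector, and a hub
#' that is also a connector is a network hub.
#'
#' @param net a [bipartite_network()].
#' @param partition a `module_partition` covering `net`.
#' @param z_hub hub threshold on `z` (default 2.5).
#' @param c_connector connector threshold on `c` (default 0.62).
#' @param guild_standardise standardise `z` within module x guild
#'   (default `TRUE`); `FALSE` pools both guilds of a module, for
#'   comparability with the original unipartite formulation.
#' @return A data frame of class `taxon_roles` with columns `label`,
#'   `guild` (`"insect"`/`"host"`), `module`, `degree`, `z_within`,
#'   `c_among` and `role` (`"peripheral"`, `"connector"`, `"module hub"`,
#'   `"network hub"`).  Nodes in a module whose guild-wise degree SD is 0
#'   get `z_within = 0`; isolated nodes get `c_among = 0`.
#' @export
compute_roles <- function(net, partition, z_hub = 2.5, c_connector = 0.62,
                          guild_standardise = TRUE) {
  stopifnot(inherits(net, "bipartite_network"),
            inherits(partition, "module_partition"))
  a <- net$adjacency
  g <- partition$assignment
  labs <- c(net$insect_labels, net$host_labels)
  guild <- rep(c("insect", "host"), c(nrow(a), ncol(a)))
  gi <- g[net$insect_labels]; gh <- g[net$host_labels]
  mods <- sort(unique(as.integer(g)))
  # links of every node into every module (opposite guild only)
  ind_h <- 1 * outer(as.integer(gh), mods, "==")   # hosts x modules
  ind_i <- 1 * outer(as.integer(gi), mods, "==")   # insects x modules
  to_mod <- rbind(a %*% ind_h, t(a) %*% ind_i)
  rownames(to_mod) <- labs
  own <- as.integer(g[labs])
  k_in <- to_mod[cbind(seq_along(labs), match(own, mods))]
  deg <- c(rowSums(a), colSums(a))
  # z: standardise k_in within module (x guild)
  grp <- if (guild_standardise) paste(own, guild) else as.character(own)
  mu <- stats::ave(k_in, grp, FUN = mean)
  sdv <- stats::ave(k_in, grp, FUN = function(v)
    if (length(v) > 1) stats::sd(v) else 0)
  z <- ifelse(sdv > 0, (k_in - mu) / sdv, 0)
  # c: participation across modules
  frac2 <- (to_mod / pmax(deg, 1))^2
  c_among <- ifelse(deg > 0, 1 - rowSums(frac2), 0)
  role <- ifelse(z >= z_hub,
                 ifelse(c_among > c_connector, "network hub", "module hub"),
                 ifelse(c_among > c_connector, "connector", "peripheral"))
  out <- data.frame(label = labs, guild = guild, module = own,
                    degree = as.integer(deg), z_within = z,
                    c_among = c_among, role = role,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("taxon_roles", "data.frame")
  out
}

#' @export
print.taxon_roles <- function(x, ...) {
  hubs <- x[x$role %in% c("module hub", "network hub"), ]
  NextMethod()
  if (nrow(hubs) > 0)
    cat(sprintf("\n%d hub(s): %s\n", nrow(hubs),
                paste(sprintf("%s (%s)", hubs$label, hubs$role), collapse = ", ")))
  invisible(x)
}

#' Write taxon roles as TSV
#'
#' @param roles a [compute_roles()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_roles <- function(roles, path) {
  utils::write.table(roles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
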