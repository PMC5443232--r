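# Network topology statistics for protein-protein interaction graphs:
# degree distribution P(k), per-degree clustering C(k), neighborhood
# connectivity Cn(kn), power-law exponent fits, hub identification and the
# hierarchical / assortative classification built on them.

as_simple_graph <- function(network) {
  if (!igraph::is_igraph(network)) {
    stop("`network` must be an igraph graph (see read_edgelist())")
  }
  g <- network
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  n_before <- igraph::ecount(g)
  g <- igraph::simplify(g)
  if (igraph::ecount(g) < n_before) {
    warning("dropped ", n_before - igraph::ecount(g),
            " self-loop/duplicate edge(s)")
  }
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- sprintf("v%04d", seq_len(igraph::vcount(g)))
  }
  g
}

#' Read an undirected network from an edge-list TSV
#'
#' Expects two tab-separated columns of node ids (an optional third score
#' column is ignored). Self-loops and duplicate edges (including the same
#' edge listed in both directions) are dropped with a warning.
#'
#' @param path TSV file path.
#' @return A simple undirected [igraph::igraph] graph.
#' @export
read_edgelist <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("edge list needs two columns")
  g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
  as_simple_graph(g)
}

#' Write a network as an edge-list TSV
#' @param network An igraph graph.
#' @param path Output TSV path.
#' @export
write_edgelist <- function(network, path) {
  el <- igraph::as_edgelist(network)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Degree distribution P(k)
#'
#' P(k) = n_k / N, the fraction of nodes having degree k; the values sum
#' to 1.
#'
#' @param network A simple undirected igraph graph.
#' @return Named numeric vector, names are the observed degrees.
#' @export
degree_distribution <- function(network) {
  g <- as_simple_graph(network)
  if (igraph::vcount(g) < 1) stop("empty network")
  k <- igraph::degree(g)
  tab <- table(k)
  stats::setNames(as.numeric(tab) / igraph::vcount(g), names(tab))
}

node_degrees <- function(g) {
  stats::setNames(igraph::degree(g), igraph::V(g)$name)
}

#' Per-degree clustering coefficient profile C(k)
#'
#' For each node of degree k >= 2 the local clustering coefficient is
#' C = 2E / \[k (k - 1)\], where E is the number of edges among the node's
#' neighbors; nodes of the same degree are averaged into the profile value
#' for that degree class. Nodes with k < 2 have no defined coefficient and
#' are excluded.
#'
#' @param network A simple undirected igraph graph.
#' @return Named numeric vector, degree class -> mean C; per-node values in
#'   attribute `per_node`.
#' @export
clustering_profile <- function(network) {
  g <- as_simple_graph(network)
  k <- node_degrees(g)
  adj <- igraph::as_adj_list(g)
  nbr <- lapply(adj, function(v) igraph::V(g)$name[v])
  names(nbr) <- igraph::V(g)$name
  eligible <- names(k)[k >= 2]
  cc <- vapply(eligible, function(v) {
    nb <- nbr[[v]]
    # edges among neighbors: half the directed adjacency count
    e <- sum(vapply(nb, function(u) sum(nbr[[u]] %in% nb), numeric(1))) / 2
    2 * e / (k[[v]] * (k[[v]] - 1))
  }, numeric(1))
  if (length(cc) == 0) {
    out <- stats::setNames(numeric(0), character(0))
    attr(out, "per_node") <- cc
    return(out)
  }
  prof <- tapply(cc, k[eligible], mean)
  out <- stats::setNames(as.numeric(prof), names(prof))
  attr(out, "per_node") <- cc
  out
}

#' Neighborhood connectivity profile Cn(kn)
#'
#' For each node, the mean degree of its neighbors; nodes of the same degree
#' kn are averaged into the profile value Cn(kn). This realizes the average
#' over the conditional degree-degree distribution: a decreasing profile
#' (positive power-law exponent) signals hierarchy, an increasing one
#' (negative exponent) assortative mixing. Isolated nodes are skipped with a
#' warning.
#'
#' @param network A simple undirected igraph graph.
#' @return Named numeric vector, degree class -> Cn; per-node values in
#'   attribute `per_node`.
#' @export
neighborhood_connectivity <- function(network) {
  g <- as_simple_graph(network)
  k <- node_degrees(g)
  if (any(k == 0)) {
    warning(sum(k == 0), " isolated node(s) skipped")
  }
  adj <- igraph::as_adj_list(g)
  names(adj) <- igraph::V(g)$name
  eligible <- names(k)[k >= 1]
  nc <- vapply(eligible, function(v) {
    mean(k[as.numeric(adj[[v]])])
  }, numeric(1))
  prof <- tapply(nc, k[eligible], mean)
  out <- stats::setNames(as.numeric(prof), names(prof))
  attr(out, "per_node") <- nc
  out
}

#' Power-law exponent by log-log least squares
#'
#' Fits log10(y) = a + b log10(x) by ordinary least squares over the
#' positive points of a profile and reports the exponent as -b, so that a
#' profile following y ~ x^-e returns e (positive for decaying profiles).
#' Zero or negative y values are dropped (log undefined) and counted.
#'
#' @param points Named numeric vector (names = x, values = y) or a two-column
#'   matrix/data frame of (x, y).
#' @param min_points Minimum number of positive points required.
#' @return A `power_law_fit` list: `exponent`, `r_squared`, `n_points`,
#'   `n_dropped`, `intercept`.
#' @export
power_law_fit <- function(points, min_points = 3) {
  if (is.matrix(points) || is.data.frame(points)) {
    x <- as.numeric(points[, 1])
    y <- as.numeric(points[, 2])
  } else {
    x <- as.numeric(names(points))
    y <- as.numeric(points)
  }
  if (any(is.na(x)) || any(x <= 0)) stop("all x values must be positive")
  keep <- y > 0
  n_dropped <- sum(!keep)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < min_points) {
    stop("fewer than ", min_points, " positive points (",
         length(x), " available, ", n_dropped, " dropped)")
  }
  lx <- log10(x)
  ly <- log10(y)
  fit <- stats::lm(ly ~ lx)
  sstot <- sum((ly - mean(ly))^2)
  r2 <- if (sstot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sstot
  structure(
    list(exponent = -unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         n_points = length(x),
         n_dropped = n_dropped),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("power_law_fit: exponent", signif(x$exponent, 4),
      "r2", signif(x$r_squared, 4), "on", x$n_points, "points\n")
  invisible(x)
}

#' Identify network hubs
#'
#' Ranks nodes by degree (ties broken lexicographically by node id) and
#' selects hubs either as nodes whose degree strictly exceeds
#' mean + 2 SD of the degree distribution (`"sigma"`, the default; a regular
#' graph therefore has no hubs) or as the `n` highest-degree nodes
#' (`"top_n"`).
#'
#' @param network A simple undirected igraph graph with >= 2 nodes.
#' @param rule `"sigma"` or `"top_n"`.
#' @param n Number of hubs for `"top_n"`.
#' @return A `hub_report` list: `ranking` (data frame of node, degree) and
#'   `hubs` (character vector under the active rule).
#' @export
identify_hubs <- function(network, rule = c("sigma", "top_n"), n = 1) {
  rule <- match.arg(rule)
  g <- as_simple_graph(network)
  if (igraph::vcount(g) < 2) stop("need >= 2 nodes")
  k <- node_degrees(g)
  ord <- order(-k, names(k))
  ranking <- data.frame(node = names(k)[ord], degree = unname(k[ord]),
                        stringsAsFactors = FALSE)
  hubs <- if (rule == "sigma") {
    thr <- mean(k) + 2 * stats::sd(k)
    ranking$node[ranking$degree > thr]
  } else {
    ranking$node[seq_len(min(n, nrow(ranking)))]
  }
  structure(list(ranking = ranking, hubs = hubs, rule = rule),
            class = "hub_report")
}

#' Classify network topology from the three power-law exponents
#'
#' Applies the decision rules used for interaction networks: with gamma the
#' degree-distribution exponent, beta the clustering-profile exponent and
#' alpha the neighborhood-connectivity exponent, a network is
#' `hierarchical` when gamma < 2, beta > 0 and alpha > 0 (few high-degree
#' hubs controlling many low-degree nodes); `assortative` when alpha < 0
#' (high-degree nodes preferring each other); and
#' `scale_free_nonhierarchical` when gamma >= 2 with C(k) approximately
#' constant (|beta| < 0.1). Anything else is `inconclusive`.
#'
#' @param gamma_fit,beta_fit,alpha_fit `power_law_fit` objects or bare
#'   exponents; any may be `NA`/`NULL` for a partial rationale.
#' @return List with `class` and `rationale` (character vector).
#' @export
classify_topology <- function(gamma_fit, beta_fit, alpha_fit) {
  take <- function(f) {
    if (is.null(f)) return(NA_real_)
    if (inherits(f, "power_law_fit")) f$exponent else as.numeric(f)
  }
  gamma <- take(gamma_fit)
  beta <- take(beta_fit)
  alpha <- take(alpha_fit)
  rationale <- c(
    if (!is.na(gamma)) sprintf("gamma = %.3g (%s 2)", gamma,
                               if (gamma < 2) "<" else ">="),
    if (!is.na(beta)) sprintf("beta = %.3g (C(k) %s)", beta,
                              if (abs(beta) < 0.1) "~ constant"
                              else if (beta > 0) "decays with k"
                              else "grows with k"),
    if (!is.na(alpha)) sprintf("alpha = %.3g (%s)", alpha,
                               if (alpha > 0) "hierarchical signature"
                               else if (alpha < 0) "assortative signature"
                               else "flat")
  )
  cls <- if (!is.na(alpha) && alpha < 0) {
    "assortative"
  } else if (!is.na(gamma) && !is.na(beta) && !is.na(alpha) &&
             gamma < 2 && beta > 0 && alpha > 0) {
    "hierarchical"
  } else if (!is.na(gamma) && !is.na(beta) &&
             gamma >= 2 && abs(beta) < 0.1) {
    "scale_free_nonhierarchical"
  } else {
    "inconclusive"
  }
  list(class = cls, rationale = rationale)
}

#' Full topology profile of a network
#'
#' Convenience wrapper computing the three profiles, their power-law fits
#' and the resulting classification in one call.
#'
#' @param network A simple undirected igraph graph.
#' @param min_points Minimum positive points per fit; profiles with fewer
#'   points yield `NULL` fits and a partial classification.
#' @return List with `degree_distribution`, `clustering_profile`,
#'   `neighborhood_profile`, `fits` (gamma/beta/alpha) and `classification`.
#' @export
topology_profile <- function(network, min_points = 3) {
  g <- as_simple_graph(network)
  pk <- degree_distribution(g)
  ck <- clustering_profile(g)
  cn <- neighborhood_connectivity(g)
  safe_fit <- function(p) {
    tryCatch(power_law_fit(p, min_points), error = function(e) NULL)
  }
  fits <- list(gamma = safe_fit(pk), beta = safe_fit(ck), alpha = safe_fit(cn))
  list(
    degree_distribution = pk,
    clustering_profile = ck,
    neighborhood_profile = cn,
    fits = fits,
    classification = classify_topology(fits$gamma, fits$beta, fits$alpha)
  )
}
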