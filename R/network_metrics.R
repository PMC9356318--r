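#' Network-level measures of a contact network
#'
#' Computes the standard graph summaries used to characterize hospital
#' colocation networks: node and edge counts, mean and SD degree, density,
#' diameter, mean betweenness, mean closeness, and modularity.
#'
#' Degree, density, diameter, betweenness and closeness are computed on
#' the simple unweighted graph underlying the weighted network; diameter,
#' betweenness and closeness are taken over the largest connected
#' component (monthly networks are often disconnected, where a global
#' diameter would be infinite). Closeness is normalized, `(n-1) / sum of
#' distances`, so it lies in [0, 1]. Modularity comes from greedy
#' modularity maximization (`igraph::cluster_fast_greedy`) on the weighted
#' graph; the `community_method` column records this. A single-node
#' network has density and diameter 0; a network with no edges reports
#' modularity as `NA` with `flag = "no_edges"`.
#'
#' @param network A [build_network()] result.
#' @return A one-row tibble: `hospital_id`, `n_nodes`, `n_edges`,
#'   `mean_degree`, `sd_degree`, `density`, `diameter`,
#'   `mean_betweenness`, `mean_closeness`, `modularity`,
#'   `community_method`, `flag`.
#' @export
#' @examples
#' b <- generate_bundle(archetype_config("uniform_adult", 150, seed = 3))
#' net <- build_network(b, "H-uniform_adult", as.Date(c("2017-01-01", "2017-01-30")))
#' compute_metrics(net)
compute_metrics <- function(network) {
  stopifnot(inherits(network, "contact_network"))
  g <- as_igraph(network, weighted = TRUE)
  n <- igraph::vcount(g)
  if (n < 1) stop("network has no nodes", call. = FALSE)
  m <- igraph::ecount(g)

  deg <- igraph::degree(g)
  density <- if (n >= 2) 2 * m / (n * (n - 1)) else 0

  comp <- igraph::components(g)
  giant_ids <- which(comp$membership == which.max(comp$csize))
  giant <- igraph::induced_subgraph(g, giant_ids)
  ng <- igraph::vcount(giant)

  diameter <- if (ng >= 2) {
    igraph::diameter(giant, weights = NA, unconnected = FALSE)
  } else {
    0
  }
  mean_betw <- if (ng >= 2) {
    mean(igraph::betweenness(giant, weights = NA, directed = FALSE))
  } else {
    0
  }
  mean_close <- if (ng >= 2) {
    mean(igraph::closeness(giant, weights = NA, normalized = TRUE))
  } else {
    0
  }

  flag <- ""
  if (m == 0) {
    modularity <- NA_real_
    flag <- "no_edges"
  } else {
    comm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
    modularity <- igraph::modularity(g, igraph::membership(comm),
      weights = igraph::E(g)$weight
    )
  }

  tibble::tibble(
    hospital_id = network$hospital_id,
    n_nodes = n,
    n_edges = m,
    mean_degree = if (n > 0) 2 * m / n else 0,
    sd_degree = if (n > 1) stats::sd(deg) else 0,
    density = density,
    diameter = as.numeric(diameter),
    mean_betweenness = mean_betw,
    mean_closeness = mean_close,
    modularity = modularity,
    community_method = "fast_greedy",
    flag = flag
  )
}

#' Association between a network measure and hospital size
#'
#' Fits an ordinary least-squares linear model (Gaussian identity link) of
#' a network measure on hospital size, and reports the slope rescaled per
#' 100 patients with its two-sided p-value and 95% t-based confidence
#' interval — the reporting convention for effects of hospital size on
#' contact-network structure.
#'
#' @param data Data frame with one row per hospital (or hospital-window).
#' @param size,value Column names (strings) of the hospital size covariate
#'   (unique patients in the window) and the measure; defaults `"size"`
#'   and `"value"`.
#' @return An object of class `size_regression`; `tidy()` gives the
#'   per-100-patient slope with CI and p-value, `glance()` the usual model
#'   fit summaries.
#' @export
#' @examples
#' d <- data.frame(size = seq(500, 5000, length.out = 24))
#' d$value <- 0.5 - 0.0002 * d$size + rnorm(24, 0, 0.005)
#' fit <- metric_size_regression(d)
#' tidy(fit)
metric_size_regression <- function(data, size = "size", value = "value") {
  data <- tibble::as_tibble(data)
  stopifnot(size %in% names(data), value %in% names(data))
  d <- tibble::tibble(size = data[[size]], value = data[[value]])
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 3) stop("need at least 3 hospitals to fit", call. = FALSE)
  if (stats::sd(d$size) == 0) {
    stop("degenerate design: all hospital sizes are equal", call. = FALSE)
  }
  fit <- stats::lm(value ~ size, data = d)
  structure(
    list(fit = fit, n = nrow(d)),
    class = "size_regression"
  )
}

#' @describeIn metric_size_regression One-row tibble with
#'   `slope_per_100`, `conf_low`, `conf_high` (95%), `p_value`, `n`.
#' @param x,object A `size_regression`.
#' @param ... Unused.
#' @export
tidy.size_regression <- function(x, ...) {
  sm <- stats::coef(summary(x$fit))
  ci <- stats::confint(x$fit, "size", level = 0.95)
  tibble::tibble(
    slope_per_100 = sm["size", "Estimate"] * 100,
    conf_low = ci[1] * 100,
    conf_high = ci[2] * 100,
    p_value = sm["size", "Pr(>|t|)"],
    n = x$n
  )
}

#' @describeIn metric_size_regression Model-level fit summary
#'   (`r.squared`, `sigma`, `df_residual`, `n`).
#' @export
glance.size_regression <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(
    r_squared = sm$r.squared,
    sigma = sm$sigma,
    df_residual = x$fit$df.residual,
    n = x$n
  )
}

#' @export
print.size_regression <- function(x, ...) {
  td <- tidy(x)
  cat(
    "<size_regression> slope per 100 patients: ",
    format(td$slope_per_100, digits = 4),
    " (95% CI ", format(td$conf_low, digits = 4), " to ",
    format(td$conf_high, digits = 4), "), p = ",
    format.pval(td$p_value, digits = 3), ", n = ", td$n, "\n",
    sep = ""
  )
  invisible(x)
}
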