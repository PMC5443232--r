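#' Core/pangenome rarefaction over random genome orderings
#'
#' Genomes are added in random order; after each addition the core genome is
#' the number of gene families present in every genome sampled so far and
#' the pangenome is the number present in at least one. The experiment is
#' repeated over `n_permutations` random orderings (default 10, the
#' conventional sampling depth for these trend curves).
#'
#' @param matrix Presence/absence matrix, families x genomes (values > 0
#'   mean presence), as from [presence_absence()].
#' @param n_permutations Number of random genome orderings.
#' @param seed Integer seed.
#' @return A `rarefaction` object: `n_genomes_axis` (1..G), `core_sizes` and
#'   `pan_sizes` (permutations x G matrices), `n_permutations`, `seed`.
#' @export
rarefy <- function(matrix, n_permutations = 10, seed = 1) {
  G <- ncol(matrix)
  if (G < 2) stop("rarefaction needs >= 2 genomes")
  stopifnot(n_permutations >= 1)
  pres <- matrix > 0
  core <- pan <- base::matrix(NA_integer_, n_permutations, G)
  with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      ord <- sample.int(G)
      cums <- t(apply(pres[, ord, drop = FALSE], 1, cumsum))
      target <- base::matrix(seq_len(G), nrow(cums), G, byrow = TRUE)
      core[p, ] <- colSums(cums == target)
      pan[p, ] <- colSums(cums >= 1L)
    }
  })
  # structural invariants of the sampling scheme
  stopifnot(all(apply(core, 1, function(x) all(diff(x) <= 0))),
            all(apply(pan, 1, function(x) all(diff(x) >= 0))))
  structure(
    list(n_genomes_axis = seq_len(G), core_sizes = core, pan_sizes = pan,
         n_permutations = n_permutations, seed = seed),
    class = "rarefaction"
  )
}

#' @export
print.rarefaction <- function(x, ...) {
  G <- length(x$n_genomes_axis)
  cat("rarefaction:", x$n_permutations, "permutations over", G, "genomes;",
      "final core", mean(x$core_sizes[, G]), "pan", mean(x$pan_sizes[, G]),
      "\n")
  invisible(x)
}

#' Rarefaction table in long format
#' @param samples A `rarefaction` object.
#' @return Data frame with columns `permutation`, `n`, `core`, `pan`.
#' @export
rarefaction_table <- function(samples) {
  G <- length(samples$n_genomes_axis)
  data.frame(
    permutation = rep(seq_len(samples$n_permutations), each = G),
    n = rep(seq_len(G), samples$n_permutations),
    core = as.vector(t(samples$core_sizes)),
    pan = as.vector(t(samples$pan_sizes))
  )
}

new_curve_fit <- function(model, params, rss, n, fitted) {
  structure(list(model = model, params = params, rss = rss,
                 n = n, fitted = fitted),
            class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat("curve_fit [", x$model, "]: ",
      paste(names(x$params), signif(x$params, 6), sep = "=", collapse = ", "),
      "; rss=", signif(x$rss, 4), "\n", sep = "")
  invisible(x)
}

mean_curve <- function(samples, what) {
  y <- colMeans(samples[[what]])
  n <- samples$n_genomes_axis
  if (length(unique(n)) < 3) stop("need >= 3 distinct genome counts to fit")
  list(n = n, y = y)
}

#' Fit the exponential-decay core-genome curve
#'
#' Fits the Tettelin-style core model F_c(n) = kappa * exp(-n / tau) + omega
#' to the mean core size at each number of sampled genomes by nonlinear
#' least squares. omega is the asymptotic (open-ended) core size, kappa the
#' decaying amplitude and tau the decay constant in genomes. A flat core
#' signal short-circuits to kappa = 0, omega = constant.
#'
#' @param samples A `rarefaction` object.
#' @return A `curve_fit` with `params` kappa, tau, omega and the residual
#'   sum of squares over the mean curve.
#' @export
fit_core_decay <- function(samples) {
  mc <- mean_curve(samples, "core_sizes")
  n <- mc$n
  y <- mc$y
  if (diff(range(y)) < 1e-8) {
    return(new_curve_fit("core_exponential",
                         c(kappa = 0, tau = NA_real_, omega = unname(y[1])),
                         rss = 0, n = n, fitted = y))
  }
  omega0 <- min(y)
  start <- list(kappa = max(y[1] - omega0, 1e-6), tau = max(n) / 3,
                omega = omega0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ kappa * exp(-n / tau) + omega,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop("core curve fit did not converge (last start: ",
           paste(names(start), signif(unlist(start), 4), sep = "=",
                 collapse = ", "), "): ", conditionMessage(e))
    }
  )
  cf <- stats::coef(fit)
  new_curve_fit("core_exponential",
                c(kappa = unname(cf["kappa"]), tau = unname(cf["tau"]),
                  omega = unname(cf["omega"])),
                rss = sum(stats::residuals(fit)^2), n = n,
                fitted = stats::fitted(fit))
}

#' Fit the pangenome growth curve
#'
#' Two models are offered for the mean pangenome size as genomes accumulate:
#' the Heaps-law power model pan(n) = K * n^gamma (default; gamma > 0
#' indicates an open pangenome) and an exponential-plus-linear model
#' pan(n) = kappa * exp(-n / tau) + tg * n + C whose linear term `tg` is the
#' asymptotic number of new genes per added genome.
#'
#' @param samples A `rarefaction` object.
#' @param model `"heaps_power"` or `"exponential_linear"`.
#' @return A `curve_fit`.
#' @export
fit_pan_growth <- function(samples, model = c("heaps_power",
                                              "exponential_linear")) {
  model <- match.arg(model)
  mc <- mean_curve(samples, "pan_sizes")
  n <- mc$n
  y <- mc$y
  if (model == "heaps_power") {
    if (diff(range(y)) < 1e-8) {
      return(new_curve_fit("heaps_power",
                           c(K = unname(y[1]), gamma = 0),
                           rss = 0, n = n, fitted = y))
    }
    g0 <- log(y[length(y)] / y[1]) / log(max(n))
    start <- list(K = unname(y[1]), gamma = max(min(g0, 1), 1e-3))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ K * n^gamma, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) {
        stop("pan curve fit did not converge (last start: ",
             paste(names(start), signif(unlist(start), 4), sep = "=",
                   collapse = ", "), "): ", conditionMessage(e))
      }
    )
    cf <- stats::coef(fit)
    new_curve_fit("heaps_power",
                  c(K = unname(cf["K"]), gamma = unname(cf["gamma"])),
                  rss = sum(stats::residuals(fit)^2), n = n,
                  fitted = stats::fitted(fit))
  } else {
    lin <- stats::lm(y ~ n)
    tg0 <- unname(stats::coef(lin)[2])
    c0 <- unname(stats::coef(lin)[1])
    start <- list(kappa = max(abs(y[1] - (c0 + tg0)), 1e-6),
                  tau = max(n) / 3, tg = tg0, C = c0)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ kappa * exp(-n / tau) + tg * n + C,
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) {
        stop("pan curve fit did not converge (last start: ",
             paste(names(start), signif(unlist(start), 4), sep = "=",
                   collapse = ", "), "): ", conditionMessage(e))
      }
    )
    cf <- stats::coef(fit)
    new_curve_fit("pan_exponential_linear",
                  c(kappa = unname(cf["kappa"]), tau = unname(cf["tau"]),
                    tg = unname(cf["tg"]), C = unname(cf["C"])),
                  rss = sum(stats::residuals(fit)^2), n = n,
                  fitted = stats::fitted(fit))
  }
}
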