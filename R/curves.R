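# Gene-discovery curves over random genome orderings and exponential
# core/pan-genome model fits (Tettelin-style mean fits, Willenbrock-style
# weighted median fits) with extrapolation.

#' Sample core/pan gene-discovery curves over random genome orderings
#'
#' For each of `n_permutations` random orderings of the genomes, computes
#' the cumulative core size (clusters present in all of the first g genomes)
#' and pan size (clusters present in at least one of the first g) for
#' g = 1..G, plus the new-genes-per-added-genome increments.
#'
#' @param matrix A [pangenome_matrix()] (or a bare occupancy count matrix).
#' @param n_permutations Number of random orderings (default 100).
#' @param seed RNG seed (mandatory, for reproducibility).
#' @return An object of class `sampling_curve` with `core`, `pan`,
#'   `new_genes` (permutation x g matrices), `n_genomes`, `n_permutations`,
#'   `seed`.
#' @export
sample_gene_discovery <- function(matrix, n_permutations = 100L, seed) {
  if (missing(seed)) stop("a seed is required")
  occ <- if (inherits(matrix, "pangenome_matrix")) matrix$occupancy else matrix
  G <- ncol(occ)
  if (G < 3) stop("need at least three genomes")
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  pres <- occ > 0
  core <- matrix(0L, n_permutations, G)
  pan <- matrix(0L, n_permutations, G)
  with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      ord <- sample.int(G)
      in_all <- rep(TRUE, nrow(pres))
      in_any <- rep(FALSE, nrow(pres))
      for (g in seq_len(G)) {
        col <- pres[, ord[g]]
        in_all <- in_all & col
        in_any <- in_any | col
        core[p, g] <- sum(in_all)
        pan[p, g] <- sum(in_any)
      }
    }
  })
  new_genes <- cbind(pan[, 1, drop = FALSE],
                     pan[, -1, drop = FALSE] - pan[, -G, drop = FALSE])
  structure(list(core = core, pan = pan, new_genes = new_genes,
                 n_genomes = G, n_permutations = n_permutations,
                 seed = as.integer(seed)),
            class = "sampling_curve")
}

#' @export
print.sampling_curve <- function(x, ...) {
  cat(sprintf(paste0("<gene-discovery curve: %d genomes, %d permutations ",
                     "(seed %d)>\n"),
              x$n_genomes, x$n_permutations, x$seed))
  cat(sprintf("  mean core: %.1f -> %.1f | mean pan: %.1f -> %.1f\n",
              mean(x$core[, 1]), mean(x$core[, x$n_genomes]),
              mean(x$pan[, 1]), mean(x$pan[, x$n_genomes])))
  invisible(x)
}

# Exponential decay with offset, the common form of both fitted models.
exp_decay <- function(n, kappa, tau, offset) kappa * exp(-n / tau) + offset

# Shared nonlinear least-squares engine. y is the per-g summary (means or
# medians), w optional weights. Robust starts: offset at the last summary,
# amplitude at first - last, decay constant G/3.
fit_exp_decay <- function(g, y, w = NULL) {
  if (length(unique(g)) < 4) stop("need at least four distinct g values")
  if (max(y) - min(y) < 1e-8 || sd(y) < 1e-10) {
    return(list(kappa = 0, tau = length(g) / 3, offset = mean(y),
                degenerate = TRUE, fitted = rep(mean(y), length(g)),
                rss = sum((y - mean(y))^2)))
  }
  df <- data.frame(g = g, y = y)
  try_fit <- function(tau0) {
    minpack.lm::nlsLM(
      y ~ kappa * exp(-g / tau) + offset, data = df,
      start = list(kappa = max(y[1] - y[length(y)], 1e-3), tau = tau0,
                   offset = y[length(y)]),
      weights = if (is.null(w)) rep(1, length(y)) else w,
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  fit <- NULL
  errs <- character()
  for (tau0 in c(max(g) / 3, 2, max(g))) {
    fit <- tryCatch(try_fit(tau0), error = function(e) {
      errs <<- c(errs, conditionMessage(e)); NULL
    })
    if (!is.null(fit) && coef(fit)[["tau"]] > 0) break
    if (!is.null(fit)) { errs <- c(errs, "non-positive decay constant"); fit <- NULL }
  }
  if (is.null(fit))
    stop("exponential fit failed to converge: ",
         paste(unique(errs), collapse = "; "))
  co <- coef(fit)
  list(kappa = unname(co["kappa"]), tau = unname(co["tau"]),
       offset = unname(co["offset"]), degenerate = FALSE,
       fitted = predict(fit), rss = sum(residuals(fit)^2))
}

#' Fit the exponential core-genome decay model
#'
#' Fits F(n) = kappa * exp(-n / tau) + Omega to the sampled core-genome
#' curve. The `"tettelin"` strategy fits the per-g means (unweighted); the
#' `"willenbrock"` strategy fits the per-g medians weighted by the inverse
#' across-permutation variance at each g (zero variances are floored at the
#' smallest positive variance). Omega is the estimated asymptotic core size.
#'
#' @param curve A [sample_gene_discovery()] result.
#' @param model `"tettelin"` or `"willenbrock"`.
#' @return An object of class `core_fit` with coefficients `kappa`, `tau`,
#'   `omega`.
#' @export
fit_core <- function(curve, model = c("tettelin", "willenbrock")) {
  model <- match.arg(model)
  stopifnot(inherits(curve, "sampling_curve"))
  g <- seq_len(curve$n_genomes)
  if (model == "tettelin") {
    y <- colMeans(curve$core)
    fit <- fit_exp_decay(g, y)
  } else {
    y <- apply(curve$core, 2, median)
    v <- apply(curve$core, 2, var)
    floorv <- if (any(v > 0)) min(v[v > 0]) else 1
    fit <- fit_exp_decay(g, y, w = 1 / pmax(v, floorv))
  }
  structure(list(model = model, kappa = fit$kappa, tau = fit$tau,
                 omega = fit$offset, degenerate = fit$degenerate,
                 g = g, observed = y, fitted = fit$fitted, rss = fit$rss,
                 n_genomes = curve$n_genomes,
                 n_permutations = curve$n_permutations),
            class = c("core_fit", "pangenome_fit"))
}

#' Fit the exponential new-gene decay (pan-genome) model
#'
#' Fits n_new(g) = kappa_p * exp(-g / tau_p) + theta to the mean number of
#' new gene clusters contributed by the g-th added genome (g >= 2). theta
#' is the asymptotic number of new genes per added genome; theta > 0 is the
#' operational signature of an open pan-genome. Pan-genome extrapolation is
#' cumulative: P(N) = P(G) + sum over g = G+1..N of n_new(g).
#'
#' @param curve A [sample_gene_discovery()] result.
#' @param model Fit strategy, as in [fit_core()].
#' @return An object of class `pan_fit` with coefficients `kappa_p`,
#'   `tau_p`, `theta_rate`.
#' @export
fit_pan <- function(curve, model = c("tettelin", "willenbrock")) {
  model <- match.arg(model)
  stopifnot(inherits(curve, "sampling_curve"))
  G <- curve$n_genomes
  g <- seq.int(2L, G)
  newg <- curve$new_genes[, g, drop = FALSE]
  if (model == "tettelin") {
    y <- colMeans(newg)
    fit <- fit_exp_decay(g, y)
  } else {
    y <- apply(newg, 2, median)
    v <- apply(newg, 2, var)
    floorv <- if (any(v > 0)) min(v[v > 0]) else 1
    fit <- fit_exp_decay(g, y, w = 1 / pmax(v, floorv))
  }
  theta <- max(fit$offset, 0)
  structure(list(model = model, kappa_p = fit$kappa, tau_p = fit$tau,
                 theta_rate = theta, degenerate = fit$degenerate,
                 g = g, observed = y, fitted = fit$fitted, rss = fit$rss,
                 pan_at_G = mean(curve$pan[, G]), n_genomes = G,
                 n_permutations = curve$n_permutations),
            class = c("pan_fit", "pangenome_fit"))
}

#' @export
print.core_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Core-genome exponential fit (%s)\n", x$model))
  cat(sprintf("  F(n) = kappa * exp(-n/tau) + Omega\n"))
  cat(sprintf("  kappa = %s, tau = %s, Omega = %s   (RSS %.3g)\n",
              signif(x$kappa, digits), signif(x$tau, digits),
              signif(x$omega, digits), x$rss))
  if (x$degenerate) cat("  [degenerate: constant observed curve]\n")
  invisible(x)
}

#' @export
print.pan_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Pan-genome new-gene exponential fit (%s)\n", x$model))
  cat(sprintf("  n_new(g) = kappa_p * exp(-g/tau_p) + theta\n"))
  cat(sprintf("  kappa_p = %s, tau_p = %s, theta = %s   (RSS %.3g)\n",
              signif(x$kappa_p, digits), signif(x$tau_p, digits),
              signif(x$theta_rate, digits), x$rss))
  cat(sprintf("  pan-genome is %s (theta %s 0)\n",
              if (x$theta_rate > 0) "open" else "closed",
              if (x$theta_rate > 0) ">" else "=="))
  invisible(x)
}

#' @export
coef.core_fit <- function(object, ...) {
  c(kappa = object$kappa, tau = object$tau, omega = object$omega)
}

#' @export
coef.pan_fit <- function(object, ...) {
  c(kappa_p = object$kappa_p, tau_p = object$tau_p,
    theta_rate = object$theta_rate)
}

#' @export
predict.core_fit <- function(object, n = object$g, ...) {
  exp_decay(n, object$kappa, object$tau, object$omega)
}

#' @export
predict.pan_fit <- function(object, n = object$g, ...) {
  exp_decay(n, object$kappa_p, object$tau_p, object$theta_rate)
}

#' @export
residuals.core_fit <- function(object, ...) object$observed - object$fitted

#' @export
residuals.pan_fit <- function(object, ...) object$observed - object$fitted

#' @export
plot.pangenome_fit <- function(x, ...) {
  is_core <- inherits(x, "core_fit")
  plot(x$g, x$observed, pch = 19, cex = 0.6,
       xlab = "genomes sampled",
       ylab = if (is_core) "core gene clusters" else "new gene clusters",
       main = if (is_core) "Core-genome decay" else "New-gene decay", ...)
  lines(x$g, predict(x, x$g), col = "red", lwd = 2)
  invisible(x)
}

#' Extrapolate a fitted core or pan model to a larger genome count
#'
#' Core fits are evaluated directly at `n_target`; pan fits are accumulated:
#' the observed mean pan size at the last sampled genome plus the fitted
#' new-gene counts for every additional genome up to `n_target`.
#'
#' @param fit A `core_fit` or `pan_fit`.
#' @param n_target Genome count to extrapolate to (>= the observed count).
#' @return Expected size (scalar), with attribute `model`.
#' @export
extrapolate <- function(fit, n_target) {
  stopifnot(inherits(fit, "pangenome_fit"))
  n_target <- as.integer(n_target)
  if (n_target < fit$n_genomes)
    stop("n_target (", n_target, ") is below the observed genome count (",
         fit$n_genomes, "); interpolation is not extrapolation")
  if (inherits(fit, "core_fit")) {
    val <- exp_decay(n_target, fit$kappa, fit$tau, fit$omega)
  } else {
    extra_g <- if (n_target > fit$n_genomes)
      seq.int(fit$n_genomes + 1L, n_target) else integer()
    val <- fit$pan_at_G + sum(pmax(predict(fit, extra_g), 0))
  }
  structure(val, model = fit$model)
}

#' Write a sampled discovery curve as a long TSV
#'
#' @param curve A [sample_gene_discovery()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(curve, path) {
  G <- curve$n_genomes
  tab <- data.frame(
    permutation = rep(seq_len(curve$n_permutations), each = G),
    g = rep(seq_len(G), curve$n_permutations),
    core = as.vector(t(curve$core)), pan = as.vector(t(curve$pan)),
    new_genes = as.vector(t(curve$new_genes)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
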