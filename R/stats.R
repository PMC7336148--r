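#' Friedman test across methods
#'
#' Nonparametric test of a method effect on a metric over studies treated
#' as blocks (complete repeated measures: every study must have a value for
#' every method).
#'
#' @param value metric values (one per study x method row).
#' @param method method labels.
#' @param study study identifiers (the blocks).
#' @return A `stat_result` list: `test_name`, `statistic`, `df`, `p_value`,
#'   `correction`, `comparison`.
#' @export
friedman_across_methods <- function(value, method, study) {
  tab <- stats::xtabs(~ study + method)
  if (any(tab != 1L)) {
    bad <- rownames(tab)[apply(tab != 1L, 1L, any)]
    stop("incomplete block design; studies with missing/duplicated methods: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  ft <- stats::friedman.test(y = value, groups = factor(method),
                             blocks = factor(study))
  stat <- unname(ft$statistic)
  pval <- ft$p.value
  if (!is.finite(stat)) {
    # complete within-block ties: no evidence of a method effect
    stat <- 0
    pval <- 1
  }
  .stat_result("Friedman", stat, unname(ft$parameter), pval, "none",
               paste(levels(factor(method)), collapse = " vs "))
}

.stat_result <- function(test_name, statistic, df, p_value, correction,
                         comparison) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p_value = p_value, correction = correction,
                 comparison = comparison), class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s [%s]: statistic = %.4g, df = %s, p = %.4g (%s)\n",
              x$test_name, x$comparison, x$statistic,
              paste(x$df, collapse = "/"), x$p_value, x$correction))
  invisible(x)
}

#' Wilcoxon signed-rank test with Pratt zero handling
#'
#' Paired signed-rank test where zero differences are ranked together with
#' the nonzero ones and then dropped from the statistic (Pratt's method),
#' with a normal approximation including tie and zero corrections. All-zero
#' differences are degenerate and reported as p = 1.
#'
#' @param x,y paired samples.
#' @return List with `statistic` (W+, sum of positive ranks), `z`, `p_value`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  d <- x - y
  n <- length(d)
  r <- rank(abs(d))
  nz <- d != 0
  if (!any(nz)) {
    return(list(statistic = 0, z = 0, p_value = 1))
  }
  w_pos <- sum(r[d > 0])
  n0 <- sum(!nz)
  mu <- (n * (n + 1) - n0 * (n0 + 1)) / 4
  # tie correction over groups of tied |d| among nonzero differences
  ties <- table(r[nz])
  sig2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(ties^3 - ties) / 48
  if (sig2 <= 0) return(list(statistic = w_pos, z = 0, p_value = 1))
  z <- (w_pos - mu) / sqrt(sig2)
  list(statistic = w_pos, z = z, p_value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Pairwise Wilcoxon tests with Bonferroni correction
#'
#' Signed-rank test ([wilcoxon_signed_rank()]) for every pair of methods on
#' paired per-study values; p-values are multiplied by the number of
#' comparisons (choose(k, 2)) and capped at 1.
#'
#' @param value metric values.
#' @param method method labels.
#' @param study study identifiers pairing the values.
#' @return List of `stat_result`, one per method pair.
#' @export
pairwise_wilcoxon_bonferroni <- function(value, method, study) {
  method <- factor(method)
  wide <- stats::reshape(
    data.frame(study = study, method = method, value = value),
    idvar = "study", timevar = "method", direction = "wide")
  cols <- paste0("value.", levels(method))
  if (anyNA(wide[cols])) stop("unpaired values: every study needs every method")
  pairs <- utils::combn(levels(method), 2L, simplify = FALSE)
  m <- length(pairs)
  lapply(pairs, function(pr) {
    wt <- wilcoxon_signed_rank(wide[[paste0("value.", pr[1L])]],
                               wide[[paste0("value.", pr[2L])]])
    .stat_result("Wilcoxon signed-rank", wt$statistic, NA_integer_,
                 min(1, wt$p_value * m), sprintf("Bonferroni x%d", m),
                 paste(pr, collapse = " vs "))
  })
}

#' Gaussian GEE with exchangeable working correlation
#'
#' Generalized estimating equations for repeated measures: identity link,
#' Gaussian variance, exchangeable (or independence) working correlation
#' within clusters, and robust (sandwich) covariance for inference. Under
#' independence the coefficient estimates reduce to ordinary least squares.
#'
#' @param formula model formula.
#' @param data data.frame.
#' @param id cluster identifier (unquoted column name or vector).
#' @param corstr `"exchangeable"` or `"independence"`.
#' @param tol,max_iter convergence control for the correlation/coefficient
#'   iteration.
#' @return Object of class `gee_fit`: `coefficients`, `robust_vcov`,
#'   `naive_vcov`, `rho`, `corstr`, `terms`, `assign`, plus bookkeeping.
#' @export
gee_fit <- function(formula, data, id, corstr = c("exchangeable", "independence"),
                    tol = 1e-8, max_iter = 50L) {
  corstr <- match.arg(corstr)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  id <- eval(substitute(id), data, parent.frame())
  if (length(id) != length(y)) stop("cluster id length mismatch")
  cl <- split(seq_along(y), id)
  sizes <- lengths(cl)
  if (all(sizes == 1L) && corstr == "exchangeable") {
    warning("all clusters are singletons; falling back to independence")
    corstr <- "independence"
  }
  p <- ncol(x)
  beta <- stats::lm.fit(x, y)$coefficients
  rho <- 0
  for (iter in seq_len(max_iter)) {
    e <- y - as.vector(x %*% beta)
    phi <- sum(e^2) / (length(y) - p)
    if (phi <= .Machine$double.eps * max(1, mean(y^2))) {
      # degenerate (e.g. constant) response: the fit is exact
      rho <- 0
      break
    }
    if (corstr == "exchangeable") {
      num <- 0; den <- 0
      for (ix in cl) {
        ni <- length(ix)
        if (ni < 2L) next
        es <- e[ix]
        num <- num + (sum(es)^2 - sum(es^2)) / 2
        den <- den + ni * (ni - 1L) / 2
      }
      rho_new <- num / (phi * max(den - p, 1))
      rho_new <- max(min(rho_new, 0.99), -0.99)
    } else {
      rho_new <- 0
    }
    a_mat <- matrix(0, p, p)
    b_vec <- numeric(p)
    for (ix in cl) {
      ni <- length(ix)
      xi <- x[ix, , drop = FALSE]
      ri <- diag(1 - rho_new, ni) + matrix(rho_new, ni, ni)
      vinv <- solve(ri)
      xv <- crossprod(xi, vinv)
      a_mat <- a_mat + xv %*% xi
      b_vec <- b_vec + xv %*% y[ix]
    }
    beta_new <- solve(a_mat, b_vec)
    done <- isTRUE(max(abs(beta_new - beta)) < tol * max(1, max(abs(beta))) &&
                     abs(rho_new - rho) < tol)
    beta <- as.vector(beta_new)
    rho <- rho_new
    if (done) break
  }
  # sandwich covariance
  e <- y - as.vector(x %*% beta)
  a_mat <- matrix(0, p, p)
  meat <- matrix(0, p, p)
  for (ix in cl) {
    ni <- length(ix)
    xi <- x[ix, , drop = FALSE]
    ri <- diag(1 - rho, ni) + matrix(rho, ni, ni)
    vinv <- solve(ri)
    xv <- crossprod(xi, vinv)
    a_mat <- a_mat + xv %*% xi
    s <- as.vector(xv %*% e[ix])
    meat <- meat + tcrossprod(s)
  }
  bread <- solve(a_mat)
  robust <- bread %*% meat %*% bread
  names(beta) <- colnames(x)
  structure(list(coefficients = beta, robust_vcov = robust,
                 naive_vcov = bread * sum(e^2) / (length(y) - p),
                 rho = rho, corstr = corstr, terms = attr(mf, "terms"),
                 assign = attr(x, "assign"), n_clusters = length(cl),
                 n_obs = length(y), residuals = e),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("gee_fit (%s, rho = %.3f): %d obs in %d clusters\n",
              x$corstr, x$rho, x$n_obs, x$n_clusters))
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' Wald tests for each model term of a GEE fit
#'
#' Block Wald chi-square test (robust covariance) for the coefficients of
#' each non-intercept term.
#'
#' @param fit a [gee_fit()].
#' @return List of `stat_result`, one per term, with df equal to the number
#'   of coefficients in the term.
#' @export
gee_wald <- function(fit) {
  labels <- attr(fit$terms, "term.labels")
  lapply(seq_along(labels), function(t_ix) {
    ix <- which(fit$assign == t_ix)
    b <- fit$coefficients[ix]
    v <- fit$robust_vcov[ix, ix, drop = FALSE]
    w <- tryCatch(as.vector(t(b) %*% solve(v, b)),
                  error = function(e) {
                    # few clusters: sandwich may be rank-deficient
                    warning("robust covariance singular for term '",
                            labels[t_ix], "'; using a pseudo-inverse")
                    as.vector(t(b) %*% MASS::ginv(v) %*% b)
                  })
    .stat_result("GEE Wald", w, length(ix),
                 stats::pchisq(w, df = length(ix), lower.tail = FALSE),
                 "none", labels[t_ix])
  })
}

#' GEE comparison of threshold curves across methods
#'
#' Fits `metric ~ method * threshold` with study as the cluster variable
#' (exchangeable working correlation, robust errors) on the metrics table
#' restricted to the requested thresholds, and returns Wald chi-square
#' tests for the method effect, the threshold effect, and their
#' interaction. With 5 methods and 3 thresholds the dfs are 4, 2 and 8.
#'
#' @param metrics a [study_metrics()]-style data.frame.
#' @param dependent one of `"sd_mm"`, `"size_vertices"`, `"map_dmin_mm"`.
#' @param thresholds thresholds (percent) entering the model (default
#'   `c(30, 60, 90)`).
#' @return List with the `gee_fit` and the three Wald `stat_result`s
#'   (`method`, `threshold`, `interaction`).
#' @export
gee_threshold_model <- function(metrics, dependent = "sd_mm",
                                thresholds = c(30, 60, 90)) {
  stopifnot(dependent %in% names(metrics))
  d <- metrics[metrics$threshold_pct %in% thresholds, , drop = FALSE]
  if (!nrow(d)) stop("no rows at the requested thresholds")
  d$method <- factor(d$method)
  d$threshold <- factor(d$threshold_pct)
  d$y <- d[[dependent]]
  fit <- gee_fit(y ~ method * threshold, d, id = study_id)
  wald <- gee_wald(fit)
  names(wald) <- c("method", "threshold", "interaction")
  list(fit = fit, method = wald$method, threshold = wald$threshold,
       interaction = wald$interaction, dependent = dependent)
}

#' Per-method summaries at study and patient level
#'
#' Study-level median and quartiles of a metric per method, and the
#' patient-level version (median across each patient's studies first, then
#' quartiles across patients). An optional patient subset (e.g. the
#' postsurgical seizure-free group) restricts the rows.
#'
#' @param metrics a [study_metrics()]-style data.frame (typically filtered
#'   to one threshold, or to the threshold-independent `dmin_mm`).
#' @param metric column to summarize (default `"dmin_mm"`).
#' @param patients optional patient-id subset.
#' @return List of two data.frames, `study_level` and `patient_level`, with
#'   `method`, `n`, `q1`, `median`, `q3`.
#' @export
summarize_results <- function(metrics, metric = "dmin_mm", patients = NULL) {
  stopifnot(metric %in% names(metrics))
  d <- unique(metrics[, c("patient_id", "study_id", "method", metric)])
  if (!is.null(patients)) d <- d[d$patient_id %in% patients, , drop = FALSE]
  qline <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(n = length(v), q1 = q[1L], median = q[2L], q3 = q[3L])
  }
  study_level <- do.call(rbind, lapply(split(d, d$method), function(g) {
    cbind(data.frame(method = g$method[1L]), qline(g[[metric]]))
  }))
  pat_med <- stats::aggregate(d[[metric]],
                              by = list(method = d$method,
                                        patient_id = d$patient_id),
                              FUN = stats::median)
  patient_level <- do.call(rbind, lapply(split(pat_med, pat_med$method),
                                         function(g) {
    cbind(data.frame(method = g$method[1L]), qline(g$x))
  }))
  rownames(study_level) <- rownames(patient_level) <- NULL
  list(study_level = study_level, patient_level = patient_level)
}
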