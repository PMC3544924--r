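# restricted log-likelihood of y ~ N(Xb, V), V supplied dense.
# l_R = -1/2 [ (n-p) log 2pi + log|V| + log|X'V^-1 X| + y'Py ]
reml_loglik_dense <- function(y, X, V) {
  n <- length(y)
  p <- ncol(X)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  logdetV <- 2 * sum(log(diag(R)))
  Vi <- chol2inv(R)
  XtViX <- crossprod(X, Vi %*% X)
  ld2 <- determinant(XtViX, logarithm = TRUE)
  if (ld2$sign <= 0) return(-Inf)
  beta <- solve(XtViX, crossprod(X, Vi %*% y))
  r <- y - X %*% beta
  yPy <- drop(crossprod(r, Vi %*% r))
  -0.5 * ((n - p) * log(2 * pi) + logdetV + as.numeric(ld2$modulus) + yPy)
}

# profile restricted log-likelihood at variance ratio delta = s2_k / s2_e
# in the eigenbasis of the kernel; returns loglik and the profiled s2_e.
reml_profile_eigen <- function(log_delta, lam, ty, tX) {
  n <- length(ty)
  p <- ncol(tX)
  delta <- exp(log_delta)
  u <- delta * lam + 1
  w <- 1 / u
  sw <- sqrt(w)
  Xs <- tX * sw
  ys <- ty * sw
  qx <- qr(Xs)
  rss <- sum(qr.resid(qx, ys)^2)
  s2e <- rss / (n - p)
  ldXWX <- 2 * sum(log(abs(diag(qr.R(qx)))))
  ll <- -0.5 * ((n - p) * (log(2 * pi) + log(s2e) + 1) +
                  sum(log(u)) + ldXWX)
  list(loglik = ll, s2e = s2e, delta = delta)
}

# method-of-moments relationship matrices need not be positive
# semidefinite; clamp negative eigenvalues at zero before they enter a
# covariance model (both likelihood paths see the same projected kernel)
psd_project <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) >= -1e-12 * max(abs(e$values))) return(K)
  lam <- pmax(e$values, 0)
  V <- e$vectors %*% (lam * t(e$vectors))
  (V + t(V)) / 2
}

as_kernel_matrix <- function(k) {
  if (inherits(k, "cgsa_kinship")) k$matrix
  else if (is.matrix(k)) k
  else stop("kernels must be cgsa_kinship objects or matrices")
}

build_design <- function(n, covariates = NULL) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n)
    stop("covariate table must have one row per individual")
  for (nm in names(covariates))
    if (!is.numeric(covariates[[nm]]))
      covariates[[nm]] <- factor(covariates[[nm]])
  X <- stats::model.matrix(~ ., data = covariates)
  if (qr(X)$rank < ncol(X))
    stop("fixed-effect design is rank deficient after reference-level dropping")
  X
}

#' Fit a variance-component mixed model by REML
#'
#' Maximises the restricted likelihood of
#' `y ~ MVN(Xb, sum_k sigma2_k K_k + sigma2_e I)` over non-negative variance
#' components, one per relationship kernel plus a residual. With no kernels
#' this is the ordinary REML of the fixed-effect model (for an intercept-only
#' design, the `n - 1` sample variance). With a single kernel the kernel is
#' eigendecomposed once and the likelihood is profiled over the variance
#' ratio, making each evaluation O(n); with several kernels a bounded
#' quasi-Newton search on log-variances is run from multiple starts,
#' including a start at the residual-only solution so that adding a kernel
#' can never decrease the reported restricted log-likelihood.
#'
#' Method-of-moments relationship matrices need not be positive
#' semidefinite; every kernel is projected onto the PSD cone (negative
#' eigenvalues clamped at zero) before entering the covariance model, so
#' the reported log-likelihood refers to the projected kernels.
#'
#' @param y numeric response vector, aligned to the kernel row order.
#' @param kernels named list of `cgsa_kinship` objects or plain symmetric
#'   matrices; may be empty.
#' @param covariates optional `data.frame` of fixed-effect covariates
#'   (categorical columns are factor-coded with first-level reference
#'   dropping; an intercept is always included).
#' @param X optional explicit fixed-effect design matrix, overriding
#'   `covariates`.
#' @param eigen_K optional precomputed `eigen()` of the single kernel
#'   (symmetric), to amortise the decomposition across many fits on the same
#'   panel.
#' @param n_starts number of optimiser starts for multi-kernel models.
#' @param max_iter iteration cap for the quasi-Newton search.
#' @return An object of class `cgsa_fit`: list with `sigma2` (named vector
#'   of component estimates, last element `residual`), `loglik` (restricted
#'   log-likelihood at the estimates), `converged`, `iterations`,
#'   `algorithm`, `n`, `kernel_names`, and the `y`/`X` used (retained for
#'   audit and for [lrt()] compatibility checks).
#' @examples
#' set.seed(1)
#' g <- simulate_genotypes(80, 40, seed = 1)
#' K <- geneset_kernels(g)
#' y <- rnorm(80)
#' fit_reml(y, kernels = K["A"])
#' @export
fit_reml <- function(y, kernels = list(), covariates = NULL, X = NULL,
                     eigen_K = NULL, n_starts = 3L, max_iter = 200L) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- build_design(n, covariates)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("design matrix rows must match length(y)")
  p <- ncol(X)
  nk <- length(kernels)
  if (n < p + 2L) stop("need n >= number of fixed-effect columns + 2")
  if (nk > 0 && (is.null(names(kernels)) || any(!nzchar(names(kernels)))))
    stop("kernels must be named")
  if (anyDuplicated(names(kernels))) stop("duplicate kernel names")
  Ks <- lapply(kernels, as_kernel_matrix)
  for (nm in names(Ks)) {
    if (!identical(dim(Ks[[nm]]), c(n, n)))
      stop("kernel '", nm, "' dimension does not match length(y)")
    if (max(abs(Ks[[nm]] - diag(n))) < 1e-8)
      warning("kernel '", nm,
              "' is numerically indistinguishable from the identity; ",
              "its variance is confounded with the residual")
    Ks[[nm]] <- psd_project(Ks[[nm]])
  }

  if (nk == 0L) {
    qx <- qr(X)
    rss <- sum(qr.resid(qx, y)^2)
    s2e <- rss / (n - p)
    ldXX <- 2 * sum(log(abs(diag(qr.R(qx)))))
    ll <- -0.5 * ((n - p) * (log(2 * pi) + log(s2e) + 1) + ldXX)
    fit <- list(sigma2 = c(residual = s2e), loglik = ll, converged = TRUE,
                iterations = 0L, algorithm = "closed-form",
                n = n, kernel_names = character(0), y = y, X = X)
    class(fit) <- "cgsa_fit"
    return(fit)
  }

  if (nk == 1L) {
    K <- Ks[[1L]]
    ek <- if (!is.null(eigen_K)) eigen_K else eigen(K, symmetric = TRUE)
    lam <- pmax(ek$values, 0)
    U <- ek$vectors
    ty <- drop(crossprod(U, y))
    tX <- crossprod(U, X)

    # coarse grid over log variance ratio, then golden-section refinement;
    # the boundary delta = 0 (no kernel variance) is always a candidate
    grid <- seq(-12, 10, length.out = 23L)
    vals <- vapply(grid, function(ld)
      reml_profile_eigen(ld, lam, ty, tX)$loglik, 0)
    best <- which.max(vals)
    lo <- grid[max(1L, best - 1L)]
    hi <- grid[min(length(grid), best + 1L)]
    opt <- stats::optimize(function(ld)
      reml_profile_eigen(ld, lam, ty, tX)$loglik,
      interval = c(lo, hi), maximum = TRUE, tol = 1e-9)
    at_opt <- reml_profile_eigen(opt$maximum, lam, ty, tX)
    null_fit <- fit_reml(y, kernels = list(), X = X)
    if (null_fit$loglik >= at_opt$loglik) {
      s2 <- c(0, null_fit$sigma2[["residual"]])
      ll <- null_fit$loglik
      conv <- TRUE
    } else {
      s2 <- c(at_opt$delta * at_opt$s2e, at_opt$s2e)
      ll <- at_opt$loglik
      conv <- TRUE
    }
    names(s2) <- c(names(kernels), "residual")
    fit <- list(sigma2 = s2, loglik = ll, converged = conv,
                iterations = length(grid) + 1L,
                algorithm = "eigen-profile",
                n = n, kernel_names = names(kernels), y = y, X = X)
    class(fit) <- "cgsa_fit"
    return(fit)
  }

  # multi-kernel: bounded quasi-Newton on log variances, multi-start
  vy <- stats::var(y)
  lb <- log(vy * 1e-14)
  ub <- log(vy * 1e6)
  negll <- function(theta) {
    s2 <- exp(theta)
    V <- diag(rep(s2[nk + 1L], n))
    for (k in seq_len(nk)) V <- V + s2[k] * Ks[[k]]
    -reml_loglik_dense(y, X, V)
  }
  null_fit <- fit_reml(y, kernels = list(), X = X)
  starts <- list(
    log(c(rep(vy / (nk + 1), nk), vy / (nk + 1))),
    log(c(rep(vy * 0.01, nk), vy * 0.99)),
    log(c(rep(0.9 * vy / nk, nk), 0.1 * vy)))
  starts <- starts[seq_len(min(n_starts, length(starts)))]
  # boundary start at the residual-only solution guarantees monotonicity
  starts <- c(starts,
              list(c(rep(lb, nk), log(null_fit$sigma2[["residual"]]))))
  best <- NULL
  iters <- 0L
  for (st in starts) {
    o <- tryCatch(
      stats::optim(pmin(pmax(st, lb), ub), negll, method = "L-BFGS-B",
                   lower = lb, upper = ub,
                   control = list(maxit = max_iter, factr = 1e1,
                                  pgtol = 1e-12,
                                  ndeps = rep(1e-6, nk + 1L))),
      error = function(e) NULL)
    if (is.null(o)) next
    iters <- iters + o$counts[1L]
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("all optimiser starts failed")
  s2 <- exp(best$par)
  # snap components at the numerical floor to exactly zero
  s2[s2 <= vy * 1e-12] <- 0
  ll <- max(-negll(log(pmax(s2, vy * 1e-14))), -best$value)
  names(s2) <- c(names(kernels), "residual")
  fit <- list(sigma2 = s2, loglik = ll,
              converged = best$convergence == 0L,
              iterations = as.integer(iters),
              algorithm = "dense-lbfgsb",
              n = n, kernel_names = names(kernels), y = y, X = X)
  class(fit) <- "cgsa_fit"
  fit
}

#' @export
print.cgsa_fit <- function(x, ...) {
  cat(sprintf("cgsa_fit (%s): n = %d, restricted logLik = %.4f%s\n",
              x$algorithm, x$n, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(x$sigma2, 6))
  invisible(x)
}

#' @method logLik cgsa_fit
#' @export
logLik.cgsa_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$sigma2), class = "logLik")
}

# upper-tail probability of the boundary chi-square mixture
# sum_{k=0..q} C(q,k) 2^-q chisq_k; chisq_0 is a point mass at zero
mixture_pvalue <- function(stat, q) {
  if (stat <= 0) return(1)
  w <- choose(q, seq_len(q)) / 2^q
  sum(w * stats::pchisq(stat, df = seq_len(q), lower.tail = FALSE))
}

#' Likelihood-ratio test for variance components on the boundary
#'
#' Compares two nested REML fits sharing the response and fixed-effect
#' design, where the null fit's kernel set is a strict subset of the full
#' fit's. Because each tested variance component sits on the boundary of its
#' parameter space under the null, the test statistic
#' `2 * (logLik_full - logLik_null)` (floored at zero) is referred to the
#' binomial-weighted chi-square mixture `sum_k C(q,k) 2^-q chisq_k` for `q`
#' tested components; for a single component this is the familiar
#' `0.5 chisq_0 + 0.5 chisq_1`. A naive `chisq_q` reference (conservative)
#' is available with `mixture = FALSE`.
#'
#' @param full,null `cgsa_fit` objects from [fit_reml()].
#' @param mixture use the boundary mixture null (default) or plain
#'   `chisq_q`.
#' @param tol tolerance for detecting an optimizer failure: if the null
#'   log-likelihood exceeds the full by more than `tol`, an error advises a
#'   refit.
#' @return An object of class `cgsa_lrt`: list with `statistic`,
#'   `n_components`, `null_distribution` and `p_value` (in `(0, 1]`).
#' @export
lrt <- function(full, null, mixture = TRUE, tol = 1e-6) {
  stopifnot(inherits(full, "cgsa_fit"), inherits(null, "cgsa_fit"))
  if (full$n != null$n || !isTRUE(all.equal(full$y, null$y)) ||
      !isTRUE(all.equal(unname(full$X), unname(null$X))))
    stop("full and null fits must share the same response and fixed effects")
  if (!all(null$kernel_names %in% full$kernel_names) ||
      length(null$kernel_names) >= length(full$kernel_names))
    stop("null kernel set must be a strict subset of the full kernel set")
  q <- length(full$kernel_names) - length(null$kernel_names)
  raw <- 2 * (full$loglik - null$loglik)
  if (raw < -tol)
    stop(sprintf(paste0("null restricted log-likelihood exceeds the full ",
                        "model's by %.3g: optimizer failure, refit with ",
                        "more starts"), -raw / 2))
  stat <- max(0, raw)
  pv <- if (mixture) mixture_pvalue(stat, q)
        else if (stat <= 0) 1
        else stats::pchisq(stat, df = q, lower.tail = FALSE)
  structure(list(statistic = stat, n_components = q,
                 null_distribution = if (mixture)
                   sprintf("binomial 2^-%d chi-square mixture, df 0..%d", q, q)
                 else sprintf("chi-square df %d", q),
                 p_value = pv),
            class = "cgsa_lrt")
}

#' @export
print.cgsa_lrt <- function(x, ...) {
  cat(sprintf("LRT: statistic = %.4f, %d component(s), p = %.4g\n  null: %s\n",
              x$statistic, x$n_components, x$p_value, x$null_distribution))
  invisible(x)
}

#' Gene-set association tests for a trait
#'
#' Runs the planned sequence of nested variance-component comparisons on one
#' trait: the additive set effect (`A` versus no kernel), the dominance
#' effect given additive (`A + D` versus `A`), and the joint epistatic block
#' (`A + D + AA + AD + DD` versus `A + D`). Each comparison is a boundary
#' likelihood-ratio test via [lrt()]; both fits of every comparison are
#' retained for audit.
#'
#' @param y numeric trait vector aligned to the kernels.
#' @param kernels named list of `cgsa_kinship` objects (or matrices); names
#'   among `A`, `D`, `AA`, `AD`, `DD`. Supply at least the kernels the plan
#'   needs.
#' @param covariates optional fixed-effect covariate `data.frame` (e.g.
#'   gender and sire), factor-coded with an intercept.
#' @param plan character vector of tests to run, a subset of
#'   `c("additive", "dominance", "epistasis")`; duplicates are an error.
#' @param mixture passed to [lrt()].
#' @param eigen_A optional precomputed `eigen()` of the additive kernel.
#' @return A `data.frame` with one row per planned test: `test`, columns
#'   `statistic`, `n_components`, `p_value`, `loglik_full`, `loglik_null`,
#'   `converged`. The fitted models are attached as attribute `"fits"`.
#' @export
test_gene_set <- function(y, kernels, covariates = NULL,
                          plan = c("additive", "dominance", "epistasis"),
                          mixture = TRUE, eigen_A = NULL) {
  if (anyDuplicated(plan)) stop("duplicate entries in test plan")
  known <- c("additive", "dominance", "epistasis")
  if (!all(plan %in% known))
    stop("unknown plan entries: ", paste(setdiff(plan, known), collapse = ", "))
  need <- list(additive = "A", dominance = c("A", "D"),
               epistasis = c("A", "D", "AA", "AD", "DD"))
  for (tst in plan) {
    miss <- setdiff(need[[tst]], names(kernels))
    if (length(miss))
      stop("test '", tst, "' needs kernel(s): ", paste(miss, collapse = ", "))
  }
  X <- build_design(length(y), covariates)
  cache <- list()
  get_fit <- function(kn) {
    key <- if (length(kn)) paste(sort(kn), collapse = "+") else "(none)"
    if (is.null(cache[[key]])) {
      ek <- if (identical(kn, "A")) eigen_A else NULL
      cache[[key]] <<- fit_reml(y, kernels = kernels[kn], X = X,
                                eigen_K = ek)
    }
    cache[[key]]
  }
  comparisons <- list(
    additive = list(full = "A", null = character(0)),
    dominance = list(full = c("A", "D"), null = "A"),
    epistasis = list(full = c("A", "D", "AA", "AD", "DD"),
                     null = c("A", "D")))
  rows <- list()
  fits <- list()
  for (tst in plan) {
    cmp <- comparisons[[tst]]
    ff <- get_fit(cmp$full)
    fn <- get_fit(cmp$null)
    lt <- lrt(ff, fn, mixture = mixture)
    rows[[tst]] <- data.frame(
      test = tst,
      statistic = lt$statistic,
      n_components = lt$n_components,
      p_value = lt$p_value,
      loglik_full = ff$loglik,
      loglik_null = fn$loglik,
      converged = ff$converged && fn$converged,
      stringsAsFactors = FALSE)
    fits[[tst]] <- list(full = ff, null = fn)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
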