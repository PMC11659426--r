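#' Stepwise multiple regression on distance matrices
#'
#' Regresses a pairwise dissimilarity matrix (response) on a set of candidate
#' predictor matrices (pairwise absolute environmental differences and
#' geographic distance), each sample pair being one data point. Predictors
#' enter by forward selection: at each step every unselected candidate is fit
#' by ordinary least squares on the unfolded lower triangles together with
#' the already-selected predictors, and its coefficient's significance is
#' assessed by permuting the response matrix's rows and columns
#' simultaneously `n_perm` times and refitting (the raw-data permutation
#' variant for matrix regression). The candidate with the smallest
#' permutation p-value is added if p < `alpha`, ties broken by larger
#' absolute standardized coefficient; otherwise selection stops. An empty
#' selection is a legitimate outcome.
#'
#' Pairs with a missing value in a candidate are dropped for that candidate
#' only. A candidate collinear with the selected set is skipped with a
#' warning. Two-sided p-values on the pseudo-t statistic, add-one convention.
#'
#' @param response Labelled symmetric dissimilarity matrix (>= 4 samples).
#' @param candidates Named list of labelled symmetric predictor matrices over
#'   the same samples.
#' @param alpha Entry threshold on the permutation p-value (default 0.05).
#' @param n_perm Permutations per step (default 1000).
#' @param seed Integer seed.
#' @return An object of class `mrm_fit`: list with `selected` (ordered
#'   names), `coefficients` (intercept + slopes of the final model), `r2`,
#'   `step_p` (entry p-value per selected predictor), `candidate_p` (p-values
#'   of all candidates at the first step), `alpha`, `n_perm`, `seed`,
#'   `n_samples`. `r2_cv` is `NA` until [loso_cv_r2()] is run.
#' @export
stepwise_mrm <- function(response, candidates, alpha = 0.05, n_perm = 1000,
                         seed = NULL) {
  check_distance_matrix(response)
  n <- nrow(response)
  if (n < 4L) stop2("need at least 4 samples")
  ids <- rownames(response)
  if (length(candidates) && is.null(names(candidates)))
    stop2("candidates must be named")
  if (anyDuplicated(names(candidates))) stop2("duplicate candidate names")
  cand <- lapply(candidates, function(m) {
    if (!setequal(rownames(m), ids)) stop2("candidate labels do not match response")
    m[ids, ids]
  })
  lt <- lower.tri(response)
  y <- response[lt]
  xv <- lapply(cand, function(m) m[lt])

  fit <- with_seed(seed, {
    # one permutation set per step, reused across candidates
    selected <- character(0)
    step_p <- numeric(0)
    candidate_p <- NULL
    repeat {
      remaining <- setdiff(names(cand), selected)
      if (!length(remaining)) break
      perms <- lapply(seq_len(n_perm), function(k) sample.int(n))
      Yp <- vapply(perms, function(p) response[p, p][lt], numeric(length(y)))
      Xsel <- if (length(selected))
        do.call(cbind, xv[selected]) else NULL
      if (!is.null(Xsel)) {
        # stop once the selected set already fits (numerically) perfectly
        ks <- stats::complete.cases(Xsel)
        rs <- sum(qr.resid(qr(cbind(1, Xsel[ks, , drop = FALSE])), y[ks])^2)
        if (rs <= 1e-10 * max(sum((y[ks] - mean(y[ks]))^2), .Machine$double.eps))
          break
      }
      res <- lapply(remaining, function(nm) {
        xc <- xv[[nm]]
        keep <- !is.na(xc)
        if (!is.null(Xsel)) keep <- keep & stats::complete.cases(Xsel)
        X <- cbind(`(Intercept)` = 1, Xsel, xc)[keep, , drop = FALSE]
        colnames(X)[ncol(X)] <- nm
        qx <- qr(X)
        if (qx$rank < ncol(X)) return(NULL) # collinear
        yk <- y[keep]
        k <- ncol(X); dfree <- nrow(X) - k
        if (dfree < 1L) return(NULL)
        inv <- chol2inv(qr.R(qx))
        bc_idx <- k
        b <- qr.coef(qx, yk)
        rss <- sum(qr.resid(qx, yk)^2)
        tss <- sum((yk - mean(yk))^2)
        t_obs <- if (rss <= 1e-10 * max(tss, .Machine$double.eps))
          Inf * sign(b[bc_idx]) # numerically exact fit with this candidate
        else b[bc_idx] / sqrt(rss / dfree * inv[bc_idx, bc_idx])
        if (is.nan(t_obs)) t_obs <- 0 # 0/0: candidate adds nothing
        Bp <- qr.coef(qx, Yp[keep, , drop = FALSE])
        rssp <- colSums(qr.resid(qx, Yp[keep, , drop = FALSE])^2)
        t_perm <- Bp[bc_idx, ] / sqrt(rssp / dfree * inv[bc_idx, bc_idx])
        t_perm[is.nan(t_perm)] <- 0
        p <- (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (1 + n_perm)
        list(name = nm, p = p, b = b[bc_idx],
             std = b[bc_idx] * sd(xc[keep]) / sd(yk))
      })
      ok <- !vapply(res, is.null, logical(1))
      if (any(!ok))
        warning("skipping collinear/degenerate candidate(s): ",
                paste(remaining[!ok], collapse = ", "), call. = FALSE)
      res <- res[ok]
      if (!length(res)) break
      pvals <- vapply(res, `[[`, numeric(1), "p")
      if (is.null(candidate_p))
        candidate_p <- setNames(pvals, vapply(res, `[[`, character(1), "name"))
      best <- order(pvals, -abs(vapply(res, `[[`, numeric(1), "std")))[1L]
      if (pvals[best] >= alpha) break
      selected <- c(selected, res[[best]]$name)
      step_p <- c(step_p, pvals[best])
    }
    list(selected = selected, step_p = step_p, candidate_p = candidate_p)
  })

  # final least squares on the selected set
  if (length(fit$selected)) {
    Xf <- do.call(cbind, xv[fit$selected])
    colnames(Xf) <- fit$selected
    keep <- stats::complete.cases(Xf)
    m <- lm(y[keep] ~ Xf[keep, , drop = FALSE])
    coefs <- setNames(coef(m), c("(Intercept)", fit$selected))
    r2 <- 1 - sum(residuals(m)^2) / sum((y[keep] - mean(y[keep]))^2)
  } else {
    coefs <- c(`(Intercept)` = mean(y))
    r2 <- 0
  }
  structure(list(selected = fit$selected, coefficients = coefs, r2 = r2,
                 r2_cv = NA_real_, step_p = setNames(fit$step_p, fit$selected),
                 candidate_p = fit$candidate_p, alpha = alpha,
                 n_perm = n_perm, seed = seed, n_samples = n),
            class = "mrm_fit")
}

#' @export
print.mrm_fit <- function(x, ...) {
  cat(sprintf("Stepwise regression on distance matrices (n = %d samples, %d pairs)\n",
              x$n_samples, x$n_samples * (x$n_samples - 1) / 2))
  if (!length(x$selected)) {
    cat("  no predictor reached the entry threshold alpha =", x$alpha, "\n")
  } else {
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
    print(round(x$coefficients, 6))
    cat(sprintf("  R2 = %.4f, cross-validated R2 = %s\n", x$r2,
                ifelse(is.na(x$r2_cv), "not computed", sprintf("%.4f", x$r2_cv))))
  }
  invisible(x)
}

#' Leave-one-sample-out cross-validated R2 for a distance regression
#'
#' For each sample s, the selected model is refit on all pairs not involving
#' s and used to predict the pairs involving s; the cross-validated fraction
#' of explained variance is `1 - SS_pred / SS_tot` over the pooled held-out
#' pairs (each pair is held out twice, once per endpoint). May be negative
#' when the model predicts worse than the held-out mean.
#'
#' @param response Labelled symmetric dissimilarity matrix (>= 4 samples).
#' @param fit An [stepwise_mrm()] fit with at least one selected predictor.
#' @param candidates The candidate set the fit was built from.
#' @return The cross-validated R2 (also stored when called via
#'   [run_full_analysis()]).
#' @export
loso_cv_r2 <- function(response, fit, candidates) {
  check_distance_matrix(response)
  stopifnot(inherits(fit, "mrm_fit"))
  if (!length(fit$selected)) stop2("fit has no selected predictors")
  n <- nrow(response)
  if (n < 4L) stop2("need at least 4 samples")
  ids <- rownames(response)
  cand <- lapply(candidates[fit$selected], function(m) m[ids, ids])
  pair_i <- row(response)[lower.tri(response)]
  pair_j <- col(response)[lower.tri(response)]
  y <- response[lower.tri(response)]
  X <- do.call(cbind, lapply(cand, function(m) m[lower.tri(m)]))
  colnames(X) <- fit$selected
  preds <- rep(NA_real_, length(y))
  held_y <- held_p <- numeric(0)
  for (s in seq_len(n)) {
    test <- pair_i == s | pair_j == s
    train <- !test & stats::complete.cases(X)
    if (sum(train) <= ncol(X) + 1L) stop2("too few training pairs for sample ", ids[s])
    b <- qr.coef(qr(cbind(1, X[train, , drop = FALSE])), y[train])
    ok <- test & stats::complete.cases(X)
    yhat <- cbind(1, X[ok, , drop = FALSE]) %*% b
    held_y <- c(held_y, y[ok])
    held_p <- c(held_p, yhat)
  }
  1 - sum((held_y - held_p)^2) / sum((held_y - mean(held_y))^2)
}
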