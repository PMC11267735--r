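## Principal component analysis of food-group intake patterns, with
## cross-validated predictive Q2.
##
## Preprocessing follows the auto-transform convention of chemometrics
## software: log10(x + offset) to tame right-skew and admit zeros, then
## column centring and unit-variance scaling so every food group carries
## equal weight. R2 is the cumulative explained variance of the
## eigen-decomposition; Q2 = 1 - PRESS/SS, where PRESS accumulates squared
## prediction errors over seven interleaved ("venetian blinds") deletion
## groups: every seventh cell of the preprocessed matrix, in row-major
## order, is held out in turn and predicted from a model fitted without it.
## Held-out cells require a PCA that tolerates missing values, which the
## NIPALS algorithm provides.

# NIPALS PCA on a matrix that may contain NAs. Returns scores T (n x k) and
# loadings P (p x k); X is assumed already centred/scaled.
.nipals <- function(X, k, max_iter = 1000, tol = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  Tm <- matrix(0, n, k); Pm <- matrix(0, p, k)
  obs <- !is.na(X)
  Xr <- X
  Xr[!obs] <- 0
  for (a in seq_len(k)) {
    t_vec <- Xr[, which.max(colSums(Xr^2))]
    for (iter in seq_len(max_iter)) {
      # p_j = sum_i x_ij t_i / sum_i t_i^2 over observed cells
      pw <- crossprod(Xr, t_vec) / crossprod(obs, t_vec^2)
      pw[!is.finite(pw)] <- 0
      pw <- pw / sqrt(sum(pw^2))
      t_new <- (Xr %*% pw) / (obs %*% pw^2)
      t_new[!is.finite(t_new)] <- 0
      if (sum((t_new - t_vec)^2) < tol * sum(t_new^2)) {
        t_vec <- t_new
        break
      }
      t_vec <- t_new
    }
    Tm[, a] <- t_vec
    Pm[, a] <- pw
    Xr <- Xr - tcrossprod(t_vec, pw)
    Xr[!obs] <- 0
  }
  list(scores = Tm, loadings = Pm)
}

.pca_preprocess <- function(x, log_offset = 1) {
  x <- as.matrix(x)
  if (any(x + log_offset <= 0)) {
    stop("intake matrix must be non-negative (after adding the log offset)",
         call. = FALSE)
  }
  lx <- log10(x + log_offset)
  sds <- apply(lx, 2, sd)
  drop <- sds == 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " zero-variance column(s): ",
            paste(utils::head(colnames(lx)[drop], 3), collapse = ", "))
    lx <- lx[, !drop, drop = FALSE]
  }
  scale(lx)
}

#' PCA of intake patterns with cross-validated Q2
#'
#' @param x numeric matrix or data.frame, participants x food groups
#'   (intakes/day). A `participant_id` column, if present, is dropped.
#' @param k number of components.
#' @param log_offset offset added before the log10 transform; default 1.
#' @param cv_groups number of interleaved deletion groups; default 7
#'   (every seventh observation).
#' @param cv_scheme "cells" deletes every `cv_groups`-th matrix cell in
#'   row-major order (the chemometrics convention); "rows" deletes whole
#'   participant rows instead.
#' @return list of class `ffq_pca`: `loadings`, `scores`, `r2` (cumulative,
#'   per component), `q2` (cumulative, per component), `explained` (variance
#'   fraction per component), `dropped` (zero-variance groups), `k`.
#' @export
pca_patterns <- function(x, k = 2, log_offset = 1, cv_groups = 7,
                         cv_scheme = c("cells", "rows")) {
  cv_scheme <- match.arg(cv_scheme)
  if (is.data.frame(x)) {
    x <- as.matrix(x[, setdiff(names(x), "participant_id"), drop = FALSE])
  }
  Xs <- .pca_preprocess(x, log_offset)
  n <- nrow(Xs); p <- ncol(Xs)
  if (k >= min(n, p)) stop("k must be smaller than the matrix rank bound",
                           call. = FALSE)
  sv <- svd(Xs, nu = k, nv = k)
  ss_total <- sum(Xs^2)
  explained <- sv$d^2 / ss_total
  r2 <- cumsum(explained)[seq_len(k)]
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(Xs), paste0("PC", seq_len(k)))
  colnames(scores) <- paste0("PC", seq_len(k))

  # venetian-blinds cross-validation
  press <- numeric(k)
  for (g in seq_len(cv_groups)) {
    Xg <- Xs
    if (cv_scheme == "cells") {
      idx <- which((seq_len(n * p) - 1L) %% cv_groups + 1L == g)
      # row-major cell order: cell (i, j) has index (i-1)*p + j
      rows <- (idx - 1L) %/% p + 1L
      cols <- (idx - 1L) %% p + 1L
      hold <- cbind(rows, cols)
    } else {
      rows <- which((seq_len(n) - 1L) %% cv_groups + 1L == g)
      hold <- cbind(rep(rows, each = p), rep(seq_len(p), length(rows)))
    }
    Xg[hold] <- NA
    fit <- .nipals(Xg, k)
    recon <- matrix(0, n, p)
    for (a in seq_len(k)) {
      recon <- recon + tcrossprod(fit$scores[, a], fit$loadings[, a])
      press[a] <- press[a] + sum((Xs[hold] - recon[hold])^2)
    }
  }
  q2 <- 1 - press / ss_total
  structure(list(loadings = loadings, scores = scores, r2 = r2, q2 = q2,
                 explained = explained[seq_len(k)],
                 dropped = setdiff(colnames(x), colnames(Xs)), k = k),
            class = "ffq_pca")
}

#' @export
print.ffq_pca <- function(x, ...) {
  cat("<ffq_pca> ", x$k, " component(s)\n", sep = "")
  cat("  R2 (cumulative): ", paste(sprintf("%.3f", x$r2), collapse = ", "),
      "\n", sep = "")
  cat("  Q2 (cumulative): ", paste(sprintf("%.3f", x$q2), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
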