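#' Permutation MANOVA by randomization of residuals (RRPP)
#'
#' Multivariate linear-model inference with sequential (type-I) term entry
#' and residual randomization: for each term, the reduced model containing
#' the preceding terms is fitted, its residuals are permuted as whole rows
#' and added back to the reduced fitted values, and the term's statistic is
#' recomputed on each permuted data set. The statistic is a trace-based
#' pseudo-F: `(tr(SSCP_term)/df_term) / (tr(SSCP_residual)/df_residual)`.
#' P-values are `(1 + #permuted >= observed) / (1 + n_perm)`.
#'
#' Nested factors are written with the usual formula operators (e.g.
#' `cbind(...) ~ Group/Species * Region` expands species within group);
#' sequential term order follows the formula as written.
#'
#' @param formula model formula; the left-hand side must evaluate to a
#'   numeric matrix (use `cbind()` for multiple responses).
#' @param data data.frame with the factors (rows must be complete cases).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed; mandatory for reproducible inference and
#'   recorded in the output.
#' @return data.frame of class `rrpp_manova` with one row per term: `df`,
#'   `SS` (SSCP trace), `R2`, `F`, `p`; attributes `seed`, `n_perm`,
#'   `SS_total`, `SS_residual`, `df_residual`.
#' @export
rrpp_manova <- function(formula, data, n_perm = 10000, seed = 1L) {
  mf <- stats::model.frame(formula, data)
  Y <- stats::model.response(mf)
  Y <- as.matrix(Y)
  if (any(!is.finite(Y))) stop("response contains non-finite values")
  if (any(apply(Y, 2, stats::var) < 1e-30))
    stop("zero-variance response column")
  labels <- attr(stats::terms(formula, data = data), "term.labels")
  n <- nrow(Y)
  if (n <= length(labels) + 1) stop("more model terms than observations")
  for (f in labels[!grepl(":", labels)])
    if (f %in% names(data) && is.factor(data[[f]]) &&
        nlevels(factor(data[[f]])) < 2)
      stop("factor '", f, "' has fewer than 2 levels")
  X <- stats::model.matrix(formula, mf)
  asgn <- attr(X, "assign")

  # nested designs are rank-deficient in dummy coding: drop aliased columns
  # (as lm does via pivoting); a term losing all its columns is an error
  if (qr(X)$rank < ncol(X)) {
    # left-to-right greedy keep, so sequential term order is preserved
    keep <- integer(0)
    for (jc in seq_len(ncol(X)))
      if (qr(X[, c(keep, jc), drop = FALSE])$rank == length(keep) + 1L)
        keep <- c(keep, jc)
    lost <- setdiff(seq_len(ncol(X)), keep)
    gone <- setdiff(unique(asgn[lost]), unique(asgn[keep]))
    if (length(gone) > 0)
      stop("rank-deficient design; aliased terms: ",
           paste(labels[gone], collapse = ", "))
    X <- X[, keep, drop = FALSE]
    asgn <- asgn[keep]
  }
  qr_full <- qr(X)
  Q <- qr.Q(qr_full)
  # column blocks of Q per term (sequential, in formula order)
  term_ids <- sort(unique(asgn[asgn > 0]))
  if (!identical(term_ids, seq_along(labels)))
    stop("rank-deficient design; aliased terms: ",
         paste(labels[setdiff(seq_along(labels), term_ids)], collapse = ", "))
  blocks <- lapply(term_ids, function(t) which(asgn == t))
  df_term <- lengths(blocks)
  df_res <- n - ncol(X)

  ss_decomp <- function(Ym) {
    # returns per-term SS traces and residual SS trace
    QtY <- crossprod(Q, Ym)                        # p x q
    ss_all <- rowSums(QtY^2)
    ss_terms <- vapply(blocks, function(b) sum(ss_all[b]), 0)
    ss_res <- sum(Ym^2) - sum(ss_all)
    c(ss_terms, ss_res)
  }

  obs <- ss_decomp(Y)
  ss_terms <- obs[seq_along(blocks)]
  ss_res <- obs[length(obs)]
  ss_total <- sum(scale(Y, scale = FALSE)^2)
  F_obs <- (ss_terms / df_term) / (ss_res / df_res)
  R2 <- ss_terms / ss_total

  # reduced-model fits for residual randomization (terms before each term;
  # intercept-only for the first)
  set.seed(seed)
  count_ge <- numeric(length(blocks))
  fits <- vector("list", length(blocks))
  for (ti in seq_along(blocks)) {
    cols <- c(which(asgn == 0), unlist(blocks[seq_len(ti - 1)]))
    Qr <- Q[, cols, drop = FALSE]
    fitted_r <- Qr %*% crossprod(Qr, Y)
    fits[[ti]] <- list(fitted = fitted_r, resid = Y - fitted_r)
  }
  for (p in seq_len(n_perm)) {
    idx <- sample.int(n)
    for (ti in seq_along(blocks)) {
      Ym <- fits[[ti]]$fitted + fits[[ti]]$resid[idx, , drop = FALSE]
      d <- ss_decomp(Ym)
      Fp <- (d[ti] / df_term[ti]) / (d[length(d)] / df_res)
      if (Fp >= F_obs[ti]) count_ge[ti] <- count_ge[ti] + 1
    }
  }
  pval <- (1 + count_ge) / (1 + n_perm)

  out <- data.frame(term = labels, df = df_term, SS = ss_terms, R2 = R2,
                    F = F_obs, p = pval, stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "n_perm") <- n_perm
  attr(out, "SS_total") <- ss_total
  attr(out, "SS_residual") <- ss_res
  attr(out, "df_residual") <- df_res
  class(out) <- c("rrpp_manova", "data.frame")
  out
}

#' @export
print.rrpp_manova <- function(x, ...) {
  cat(sprintf(
    "Residual-randomization permutation MANOVA (%d permutations, seed %d)\n",
    attr(x, "n_perm"), attr(x, "seed")))
  df <- as.data.frame(x)
  df$SS <- signif(df$SS, 5)
  df$R2 <- signif(df$R2, 3)
  df$F <- signif(df$F, 4)
  print(df, row.names = FALSE)
  cat(sprintf("Residual: df %d, SS %.5g; total SS %.5g\n",
              attr(x, "df_residual"), attr(x, "SS_residual"),
              attr(x, "SS_total")))
  invisible(x)
}

#' Write an rrpp_manova table as delimited text
#'
#' Records the seed and permutation count alongside the term table.
#'
#' @param x an [rrpp_manova()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manova <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#n_perm %d", attr(x, "n_perm")),
               sprintf("#seed %d", attr(x, "seed"))), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
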