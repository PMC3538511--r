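## Epistasis as a deformation of the independent penetrance matrix.
##
## The user fixes up to three cells of the increment matrix Delta (as
## percentage changes of the independent-model risk); the remaining cells
## are completed so that every row and column of Delta, weighted by the
## genotype frequencies of the other locus, sums to zero.  Those two sets of
## linear conditions are exactly what keeps the single-locus marginal risks
## -- and hence the prevalence -- unchanged by the deformation.  Residual
## freedom is resolved by minimising the variance of the relative increments
## Delta / TR over the non-user cells, so unconstrained cells move as
## proportionally alike as possible.

#' Specify epistatic increments
#'
#' Each entry requests a percentage change of the independent-model risk of
#' one combined genotype (rows index the genotype code of locus A, columns
#' of locus B; code 3 is the high-risk homozygote).
#'
#' @param entries a data frame with columns `row`, `col`, `percent`, or a
#'   list of 3-element lists/vectors.  May be empty (no epistasis).
#' @return an object of class `epistasis_spec` (validated).
#' @examples
#' epistasis_spec(data.frame(row = 3, col = 3, percent = 20))
#' @export
epistasis_spec <- function(entries = NULL) {
  if (is.null(entries) || (is.data.frame(entries) && nrow(entries) == 0L) ||
      (is.list(entries) && length(entries) == 0L)) {
    df <- data.frame(row = integer(), col = integer(), percent = numeric())
  } else if (is.data.frame(entries)) {
    df <- entries
  } else {
    df <- do.call(rbind, lapply(entries, function(e)
      data.frame(row = e[["row"]], col = e[["col"]],
                 percent = e[["percent"]])))
  }
  stopifnot(all(c("row", "col", "percent") %in% names(df)))
  validate_epistasis_spec(
    structure(df[c("row", "col", "percent")], class = c("epistasis_spec",
                                                        "data.frame")))
}

#' Validate an epistasis specification
#'
#' Enforces the placement rules that make the completion problem well
#' posed: at most three cells; no duplicates; every pair of specified cells
#' must share a row or share a column; percentages must exceed -100 (a
#' -100% change would zero the risk).
#'
#' @param spec an `epistasis_spec` (or a bare data frame with columns
#'   `row`, `col`, `percent`).
#' @return the validated spec, invisibly unchanged.
#' @export
validate_epistasis_spec <- function(spec) {
  df <- as.data.frame(spec)
  k <- nrow(df)
  if (k > 3L)
    stop_gxe("at most 3 epistatic cells may be specified (got %d)", k,
             class = "gxesim_validation_error")
  if (k) {
    if (!all(df$row %in% 1:3) || !all(df$col %in% 1:3))
      stop_gxe("epistasis rows/cols must be genotype codes in 1..3",
               class = "gxesim_validation_error")
    if (anyDuplicated(df[c("row", "col")]))
      stop_gxe("duplicate epistatic cell specified",
               class = "gxesim_validation_error")
    if (any(!is.finite(df$percent)) || any(df$percent <= -100))
      stop_gxe("epistatic percent changes must be finite and > -100",
               class = "gxesim_validation_error")
    if (k > 1L) {
      for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
        if (df$row[i] != df$row[j] && df$col[i] != df$col[j])
          stop_gxe(paste0("epistatic cells (%d,%d) and (%d,%d) share ",
                          "neither a row nor a column"),
                   df$row[i], df$col[i], df$row[j], df$col[j],
                   class = "gxesim_placement_error")
      }
    }
  }
  structure(df, class = c("epistasis_spec", "data.frame"))
}

# Solve: minimize x'Qx subject to A x = b and l <= x <= u, by an active-set
# loop on the bounds.  Dimensions are at most 9, so dense KKT solves are
# exact and cheap.
.solve_box_qp <- function(Q, A, b, l, u, tol = 1e-10) {
  nx <- ncol(A)
  # consistency of the equality system
  ls0 <- tryCatch(qr.solve(A, b, tol = 1e-12), error = function(e) NULL)
  if (is.null(ls0)) {
    ls0 <- as.vector(MASS::ginv(A) %*% b)
  }
  if (max(abs(A %*% ls0 - b)) > 1e-8)
    stop_gxe(paste0("epistasis completion infeasible: user increments are ",
                    "inconsistent with the marginal-preservation constraints ",
                    "(residual %.3g)"), max(abs(A %*% ls0 - b)),
             class = "gxesim_infeasible_error")

  act_lo <- logical(nx); act_up <- logical(nx)
  solve_eq <- function(Aeq, beq) {
    K <- rbind(cbind(2 * Q, t(Aeq)),
               cbind(Aeq, matrix(0, nrow(Aeq), nrow(Aeq))))
    rhs <- c(rep(0, nx), beq)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) sol <- as.vector(MASS::ginv(K) %*% rhs)
    list(x = sol[seq_len(nx)], nu = sol[-seq_len(nx)])
  }
  for (iter in seq_len(100L)) {
    rows_lo <- which(act_lo); rows_up <- which(act_up)
    Aeq <- A; beq <- b
    for (i in rows_lo) { Aeq <- rbind(Aeq, diag(nx)[i, ]); beq <- c(beq, l[i]) }
    for (i in rows_up) { Aeq <- rbind(Aeq, diag(nx)[i, ]); beq <- c(beq, u[i]) }
    s <- solve_eq(Aeq, beq)
    x <- s$x
    viol_lo <- l - x; viol_up <- x - u
    viol_lo[act_lo] <- -Inf; viol_up[act_up] <- -Inf
    worst <- max(c(viol_lo, viol_up))
    if (worst > tol) {
      i <- which.max(c(viol_lo, viol_up))
      if (i <= nx) act_lo[i] <- TRUE else act_up[i - nx] <- TRUE
      if (any(act_lo & act_up))
        stop_gxe("epistasis completion infeasible: a cell's lower and upper risk bounds conflict",
                 class = "gxesim_infeasible_error")
      next
    }
    # KKT sign check on active bounds; grad = mu_e * e_i + A'nu requires
    # mu >= 0 on lower bounds and <= 0 on upper bounds
    nb <- length(rows_lo) + length(rows_up)
    if (nb == 0L) return(x)
    coef <- -s$nu[nrow(A) + seq_len(nb)]
    mu_lo <- coef[seq_along(rows_lo)]
    mu_up <- if (length(rows_up)) coef[length(rows_lo) + seq_along(rows_up)] else numeric()
    bad_lo <- rows_lo[mu_lo < -1e-9]
    bad_up <- rows_up[mu_up > 1e-9]
    if (!length(bad_lo) && !length(bad_up)) return(x)
    # release the most wrongly-signed constraint and retry
    cand <- c(bad_lo, bad_up)
    scores <- c(abs(mu_lo[mu_lo < -1e-9]), abs(mu_up[mu_up > 1e-9]))
    i <- cand[which.max(scores)]
    if (i %in% bad_lo) act_lo[i] <- FALSE else act_up[i] <- FALSE
  }
  stop_gxe("epistasis completion: active-set iteration failed to converge",
           class = "gxesim_numeric_error")
}

#' Complete the epistatic increment matrix
#'
#' Given the independent penetrance matrix and a validated epistasis
#' specification, fixes the user cells at `Delta = percent/100 * TR` and
#' completes the remaining cells so that (i) each genotype-frequency-
#' weighted row and column sum of `Delta` is zero (marginal risks and
#' prevalence are preserved) and (ii) every deformed risk stays in
#' `[0, 1]`.  Among feasible completions, the one minimising the variance
#' of the relative increments `Delta/TR` over the non-user cells is
#' returned; the objective is a convex quadratic on an affine set, so the
#' minimiser is unique and deterministic.  Cells with `TR = 0` are pinned
#' to `Delta = 0` (their relative increment is undefined) with a warning.
#'
#' @param tri a `penetrance_matrix` of kind `"independent"`.
#' @param spec an `epistasis_spec`.
#' @return an object of class `delta_matrix` with fields `delta` (3 x 3),
#'   `user_mask` (3 x 3 logical) and the genotype frequencies used.
#' @examples
#' f <- hwe_genotype_freqs(0.3)
#' s <- locus_spec("rs1", "C", 0.3, rr = 1.6, w = 0.5)
#' tri <- independent_tr(marginal_risks_from_rr(s, s, f, f, m = 0.1))
#' d <- complete_delta(tri, epistasis_spec(data.frame(row = 3, col = 3,
#'                                                    percent = 20)))
#' d$delta[3, 3] / tri$tr[3, 3]  # 0.2
#' @export
complete_delta <- function(tri, spec) {
  stopifnot(inherits(tri, "penetrance_matrix"))
  if (tri$kind != "independent")
    stop_gxe("complete_delta expects the independent penetrance matrix",
             class = "gxesim_validation_error")
  spec <- validate_epistasis_spec(spec)
  TRI <- tri$tr; pa <- tri$freqs_a; pb <- tri$freqs_b

  delta <- matrix(0, 3, 3)
  user_mask <- matrix(FALSE, 3, 3)
  out <- function(delta) {
    dimnames(delta) <- dimnames(TRI)
    structure(list(delta = delta, user_mask = user_mask,
                   freqs_a = pa, freqs_b = pb),
              class = "delta_matrix")
  }
  if (nrow(spec) == 0L) return(out(delta))  # variance minimum: no deformation

  for (i in seq_len(nrow(spec))) {
    user_mask[spec$row[i], spec$col[i]] <- TRUE
    delta[spec$row[i], spec$col[i]] <-
      spec$percent[i] / 100 * TRI[spec$row[i], spec$col[i]]
  }
  zero_tr <- TRI <= 0 & !user_mask
  if (any(zero_tr))
    warning("cells with zero independent-model risk are pinned to Delta = 0")

  # equality constraints over vec(Delta), column-major
  A6 <- matrix(0, 6, 9)
  for (i in 1:3) for (j in 1:3) {
    v <- (j - 1L) * 3L + i
    A6[i, v] <- pb[j]          # row-i weighted sum = 0
    A6[3L + j, v] <- pa[i]     # column-j weighted sum = 0
  }
  fixed <- as.vector(user_mask | zero_tr)
  dvec <- as.vector(delta)
  free <- which(!fixed)
  lo_all <- pmax(-1, -as.vector(TRI))
  up_all <- pmin(1, 1 - as.vector(TRI))
  bad <- which(fixed & (dvec < lo_all - 1e-12 | dvec > up_all + 1e-12))
  if (length(bad))
    stop_gxe(paste0("user epistatic increment at cell (%d,%d) drives the ",
                    "risk outside [0, 1]"),
             (bad[1] - 1) %% 3 + 1, (bad[1] - 1) %/% 3 + 1,
             class = "gxesim_infeasible_error")

  b <- -as.vector(A6[, fixed, drop = FALSE] %*% dvec[fixed])
  Af <- A6[, free, drop = FALSE]

  # variance-of-ratios objective over the free (non-user, nonzero-TR) cells
  trf <- as.vector(TRI)[free]
  k <- length(free)
  v <- 1 / trf
  Q <- diag(v^2, k) / k - tcrossprod(v) / k^2
  x <- .solve_box_qp(Q, Af, b, lo_all[free], up_all[free])
  dvec[free] <- x
  delta <- matrix(dvec, 3, 3)

  res <- max(abs(delta %*% pb), abs(pa %*% delta))
  if (res > 1e-9)
    stop_gxe("epistasis completion failed the consistency conditions (residual %.3g)",
             res, class = "gxesim_numeric_error")
  out(delta)
}

#' @export
print.delta_matrix <- function(x, ...) {
  cat("Epistatic increment matrix Delta (user-fixed cells marked *):\n")
  m <- matrix(sprintf("%.6g", x$delta), 3, 3)
  m[x$user_mask] <- paste0(m[x$user_mask], "*")
  print(m, quote = FALSE)
  invisible(x)
}

#' Apply an epistatic deformation to the independent penetrance matrix
#'
#' Computes `TR_E = TR_I + Delta` and re-checks that every entry lies in
#' `[0, 1]` and that the deformation preserved the marginal risks and
#' prevalence.
#'
#' @param tri a `penetrance_matrix` of kind `"independent"`.
#' @param delta a `delta_matrix` from [complete_delta()].
#' @return a `penetrance_matrix` of kind `"epistatic"`.
#' @export
apply_delta <- function(tri, delta) {
  stopifnot(inherits(tri, "penetrance_matrix"), inherits(delta, "delta_matrix"))
  tre <- tri$tr + delta$delta
  if (any(tre < -1e-12) || any(tre > 1 + 1e-12))
    stop_gxe("deformed penetrance leaves [0, 1] (range %.4g .. %.4g)",
             min(tre), max(tre), class = "gxesim_infeasible_error")
  pm <- new_penetrance_matrix(pmin(pmax(tre, 0), 1), "epistatic", tri)
  s <- penetrance_summary(pm)
  if (max(abs(s$tr_a - tri$tr_a), abs(s$tr_b - tri$tr_b),
          abs(s$prevalence - tri$m)) > 1e-9)
    stop_gxe("deformation failed to preserve marginal risks/prevalence",
             class = "gxesim_numeric_error")
  pm
}
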