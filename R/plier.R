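#' Configuration for the knowledge-constrained factorization
#'
#' @param k latent dimension (number of latent variables).
#' @param lambda1,lambda2,lambda3 penalty weights for the prior-alignment,
#'   loading-ridge and sparsity terms; `"auto"` derives lambda2 from the
#'   spectrum of the (standardized) data — `lambda2 = sigma_k^2 / sigma_1`,
#'   `lambda1 = lambda2/2` — and picks a lambda3 starting point from the
#'   scale of `C' Z0`, then adapts it toward the `frac` target.
#' @param l1_fraction elastic-net mixing for the U penalty in `(0, 1]`;
#'   1 is the pure L1 penalty, default 0.9.
#' @param frac target fraction of latent variables carrying at least one
#'   gene-set association; default 0.7.
#' @param max_iter maximum alternating iterations; default 350.
#' @param tol relative objective-change convergence tolerance; default 1e-6.
#' @param max_path maximum gene sets per latent variable; default 10.
#' @param seed integer seed recorded in the model (the solver is
#'   deterministic; the seed keeps any future stochastic extension and the
#'   archive reproducible).
#' @param standardize_rows center/scale each feature row of `D` before
#'   fitting (stored so transfers use the training scaling); default `TRUE`.
#' @return a `plier_config` list.
#' @export
plier_config <- function(k, lambda1 = "auto", lambda2 = "auto", lambda3 = "auto",
                         l1_fraction = 0.9, frac = 0.7, max_iter = 350L,
                         tol = 1e-6, max_path = 10L, seed = 1L,
                         standardize_rows = TRUE) {
  stopifnot(k >= 1, tol > 0, frac > 0, frac <= 1, max_path >= 1,
            l1_fraction > 0, l1_fraction <= 1, max_iter >= 1)
  for (nm in c("lambda1", "lambda2", "lambda3")) {
    v <- get(nm)
    if (!(identical(v, "auto") || (is.numeric(v) && v >= 0))) {
      abort(sprintf("`%s` must be a non-negative number or \"auto\".", nm))
    }
  }
  structure(list(k = as.integer(k), lambda1 = lambda1, lambda2 = lambda2,
                 lambda3 = lambda3, l1_fraction = l1_fraction, frac = frac,
                 max_iter = as.integer(max_iter), tol = tol,
                 max_path = as.integer(max_path), seed = as.integer(seed),
                 standardize_rows = standardize_rows),
            class = "plier_config")
}

#' Standardize feature rows
#'
#' Centers and scales each row to mean 0, SD 1 (denominator n-1).
#' Zero-variance rows are set to all zeros and flagged in the
#' `"constant_rows"` attribute; `"row_center"` and `"row_scale"` attributes
#' carry the applied transform.
#'
#' @param D features x samples numeric matrix, >= 2 samples.
#' @return standardized matrix with attributes.
#' @export
standardize_rows <- function(D) {
  D <- assert_matrix_like(D, "D")
  if (ncol(D) < 2L) abort("standardize_rows needs at least 2 samples.")
  ctr <- rowMeans(D)
  scl <- apply(D, 1, sd)
  const <- scl <= .Machine$double.eps * sqrt(ncol(D))
  scl[const] <- 1
  out <- (D - ctr) / scl
  out[const, ] <- 0
  attr(out, "row_center") <- ctr
  attr(out, "row_scale") <- scl
  attr(out, "constant_rows") <- rownames(D)[const] %||% which(const)
  out
}

#' Four-term factorization objective
#'
#' Evaluates
#' `||D - ZB||_F^2 + lambda1 ||Z - CU||_F^2 + lambda2 ||B||_F^2 +
#'  lambda3 |U|_1`
#' and attaches the per-term breakdown as the `"terms"` attribute.
#'
#' @param D data (features x samples), `Z` features x k, `B` k x samples,
#'   `C` features x sets, `U` sets x k.
#' @param lambda1,lambda2,lambda3 non-negative penalty weights.
#' @return non-negative scalar with attribute `terms`
#'   (`recon`, `prior`, `b_ridge`, `u_l1`).
#' @export
plier_objective <- function(D, C, Z, U, B, lambda1, lambda2, lambda3) {
  chk <- function(a, b, da, db) {
    if (da != db) abort(sprintf("shape mismatch between %s (%d) and %s (%d)",
                                a, da, b, db))
  }
  chk("D rows", "Z rows", nrow(D), nrow(Z))
  chk("Z cols", "B rows", ncol(Z), nrow(B))
  chk("D cols", "B cols", ncol(D), ncol(B))
  chk("D rows", "C rows", nrow(D), nrow(C))
  chk("C cols", "U rows", ncol(C), nrow(U))
  chk("Z cols", "U cols", ncol(Z), ncol(U))
  terms <- c(recon = sum((D - Z %*% B)^2),
             prior = lambda1 * sum((Z - C %*% U)^2),
             b_ridge = lambda2 * sum(B^2),
             u_l1 = lambda3 * sum(abs(U)))
  structure(sum(terms), terms = terms)
}

#' SVD-based initialization
#'
#' `Z0` is the positive part of the first `k` left singular vectors of `D`
#' scaled by their singular values (each component's sign chosen so the
#' positive part dominates; a column whose positive part vanishes is
#' re-seeded from the absolute values); `B0` is the corresponding right
#' factor and `U0 = 0`. Deterministic for fixed inputs and seed.
#'
#' @inheritParams plier_objective
#' @param k latent dimension, at most `min(dim(D))`.
#' @param seed integer; recorded for reproducibility.
#' @return list with `Z0`, `B0`, `U0`.
#' @export
plier_init <- function(D, C, k, seed = 1L) {
  D <- assert_matrix_like(D, "D")
  if (k > min(dim(D))) abort("k exceeds min(dim(D)); choose a smaller latent dimension.")
  set.seed(seed)
  sv <- svd(D, nu = k, nv = k)
  Zs <- sv$u %*% diag(sv$d[seq_len(k)], k)
  B0 <- t(sv$v)
  for (j in seq_len(k)) {
    if (sum(pmax(Zs[, j], 0)) < sum(pmax(-Zs[, j], 0))) {
      Zs[, j] <- -Zs[, j]
      B0[j, ] <- -B0[j, ]
    }
  }
  Z0 <- pmax(Zs, 0)
  reseed <- colSums(Z0) == 0
  Z0[, reseed] <- abs(Zs[, reseed])
  rownames(Z0) <- rownames(D)
  colnames(B0) <- colnames(D)
  U0 <- matrix(0, ncol(C), k, dimnames = list(colnames(C), NULL))
  list(Z0 = Z0, B0 = B0, U0 = U0)
}

#' Exact ridge update of the loading matrix B
#'
#' Returns the unique minimizer `B = (Z'Z + lambda2 I)^{-1} Z' D` of
#' `||D - ZB||_F^2 + lambda2 ||B||_F^2` at fixed `Z`. With `lambda2 = 0` and
#' rank-deficient `Z`, the minimum-norm solution is returned with a message.
#'
#' @inheritParams plier_objective
#' @return k x samples matrix.
#' @export
update_b <- function(D, Z, lambda2) {
  G <- crossprod(Z) + diag(lambda2, ncol(Z))
  rhs <- crossprod(Z, D)
  if (lambda2 <= 0 && rcond_sym(G) < 1e-12) {
    inform("Z'Z is rank-deficient with lambda2 = 0; returning the minimum-norm solution.")
    return(pseudo_solve(G, rhs))
  }
  solve(G, rhs)
}

rcond_sym <- function(G) {
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  lo <- min(ev); hi <- max(ev)
  if (hi <= 0) 0 else max(lo, 0) / hi
}

pseudo_solve <- function(G, rhs) {
  sv <- svd(G)
  pos <- sv$d > max(sv$d) * 1e-12
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) %*% rhs / sv$d[pos])
}

#' Projected ridge update of the latent feature matrix Z
#'
#' The unconstrained minimizer of the Z-dependent terms is
#' `(D B' + lambda1 C U)(B B' + lambda1 I)^{-1}`; its positive part is
#' returned (non-negativity of `Z`).
#'
#' @inheritParams plier_objective
#' @return features x k non-negative matrix.
#' @export
update_z <- function(D, B, C, U, lambda1) {
  G <- tcrossprod(B) + diag(lambda1, nrow(B))
  if (rcond_sym(G) < 1e-12) {
    abort("B B' + lambda1 I is singular; use lambda1 > 0.")
  }
  M <- (D %*% t(B) + lambda1 * (C %*% U)) %*% solve(G)
  Z <- pmax(M, 0)
  rownames(Z) <- rownames(D)
  Z
}

#' Non-negative elastic-net update of the gene-set weights U
#'
#' Solves, per latent variable `j`,
#' `min_{u >= 0} ||z_j - C u||^2 +
#'   lambda3 (alpha |u|_1 + (1 - alpha)/2 ||u||_2^2)`
#' by cyclic non-negative coordinate descent, warm-started from `U_init`.
#' When the support exceeds `max_path`, the largest `max_path` coefficients
#' are kept and the problem is re-solved restricted to that support.
#'
#' @inheritParams plier_objective
#' @param Z features x k latent matrix.
#' @param l1_fraction elastic-net mixing `alpha` in `(0, 1]`.
#' @param max_path maximum nonzero gene sets per latent variable.
#' @param U_init optional warm start (sets x k).
#' @param cd_tol,cd_max_sweeps inner coordinate-descent stopping rule.
#' @return sets x k non-negative matrix with per-column support <= max_path.
#' @export
update_u <- function(Z, C, lambda3, l1_fraction = 0.9, max_path = 10L,
                     U_init = NULL, cd_tol = 1e-10, cd_max_sweeps = 1000L) {
  if (!all(C %in% c(0, 1))) abort("knowledge matrix C must be binary.")
  if (lambda3 < 0) abort("lambda3 must be >= 0.")
  m <- ncol(C); k <- ncol(Z)
  CtC <- crossprod(C)
  CtZ <- crossprod(C, Z)
  U <- if (is.null(U_init)) matrix(0, m, k) else U_init
  for (j in seq_len(k)) {
    u <- nncd_column(CtC, CtZ[, j], U[, j], lambda3, l1_fraction,
                     cd_tol, cd_max_sweeps, j)
    supp <- which(u > 0)
    if (length(supp) > max_path) {
      keep <- supp[order(u[supp], decreasing = TRUE)][seq_len(max_path)]
      u2 <- numeric(m)
      u2[keep] <- nncd_column(CtC[keep, keep, drop = FALSE], CtZ[keep, j],
                              u[keep], lambda3, l1_fraction,
                              cd_tol, cd_max_sweeps, j)
      u <- u2
    }
    U[, j] <- u
  }
  dimnames(U) <- list(colnames(C), NULL)
  U
}

# coordinate descent for one non-negative elastic-net column
nncd_column <- function(CtC, ctz, u, lambda3, alpha, tol, max_sweeps, col_idx) {
  m <- length(ctz)
  diagC <- diag(CtC)
  grad_lin <- as.vector(CtC %*% u)       # CtC u, maintained incrementally
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (s in seq_len(m)) {
      num <- 2 * (ctz[s] - grad_lin[s] + diagC[s] * u[s]) - lambda3 * alpha
      den <- 2 * diagC[s] + lambda3 * (1 - alpha)
      new_u <- if (den > 0) max(0, num / den) else 0
      d <- new_u - u[s]
      if (d != 0) {
        grad_lin <- grad_lin + CtC[, s] * d
        u[s] <- new_u
        delta <- max(delta, abs(d))
      }
    }
    if (delta < tol) return(u)
  }
  warn(sprintf("update_u: coordinate descent for latent variable %d did not reach tol %.1e in %d sweeps.",
               col_idx, tol, max_sweeps))
  u
}

#' Fit the knowledge-constrained non-negative factorization
#'
#' Alternates exact ridge updates of `B`, projected ridge updates of `Z`, and
#' non-negative elastic-net updates of `U` (order B, Z, U per iteration).
#' `lambda3` is adapted by a geometric search (halving, at most 12
#' adaptation rounds) until the fraction of latent variables with at least
#' one nonzero gene-set weight reaches `frac`; it is then frozen and the
#' loop runs to convergence (relative change of the solver objective below
#' `tol`) or `max_iter` total iterations. If support decays below the
#' target during the frozen run, the search resumes with further halvings.
#'
#' @param D features x samples matrix, rows aligned with `C`.
#' @param C binary knowledge matrix from [build_knowledge()].
#' @param config a [plier_config()]; alternatively pass `k` and options via
#'   `...` which are forwarded to `plier_config()`.
#' @param k shortcut for `plier_config(k = ...)` when `config` is missing.
#' @param ... further arguments to [plier_config()].
#' @param verbose print per-iteration objectives.
#' @return a `meth_plier` model: matrices `Z`, `U`, `B`, the effective
#'   penalties, the per-iteration trace (including the objective right after
#'   the B step), convergence status and the row-standardization parameters.
#' @export
plier_fit <- function(D, C, config = NULL, k = NULL, ..., verbose = FALSE) {
  D <- assert_matrix_like(D, "D")
  C <- assert_matrix_like(C, "C")
  if (is.null(config)) {
    if (is.null(k)) abort("supply `config` or `k`.")
    config <- plier_config(k = k, ...)
  }
  stopifnot(inherits(config, "plier_config"))
  if (!is.null(rownames(D)) && !is.null(rownames(C)) &&
      !identical(rownames(D), rownames(C))) {
    bad <- head(setdiff(union(rownames(D), rownames(C)),
                        intersect(rownames(D), rownames(C))), 5)
    abort(paste0("rows of D and C are not aligned; first differing features: ",
                 paste(bad, collapse = ", ")))
  }
  k <- config$k
  if (k > nrow(D) || k > ncol(D)) abort("k must not exceed feature or sample count.")
  if (is.null(colnames(D))) colnames(D) <- paste0("S", seq_len(ncol(D)))

  row_center <- rep(0, nrow(D)); row_scale <- rep(1, nrow(D))
  if (config$standardize_rows) {
    Ds <- standardize_rows(D)
    row_center <- attr(Ds, "row_center"); row_scale <- attr(Ds, "row_scale")
    D <- Ds; attributes(D)[c("row_center", "row_scale", "constant_rows")] <- NULL
  }

  set.seed(config$seed)
  sv_d <- svd(D, nu = 0, nv = 0)$d
  lambda2 <- if (identical(config$lambda2, "auto")) sv_d[k]^2 / sv_d[1] else config$lambda2
  lambda1 <- if (identical(config$lambda1, "auto")) lambda2 / 2 else config$lambda1
  init <- plier_init(D, C, k, config$seed)
  Z <- init$Z0; B <- init$B0; U <- init$U0

  alpha <- config$l1_fraction
  if (identical(config$lambda3, "auto")) {
    # a unit-weight subproblem penalty above 2*max_s c_s'z_j / alpha zeroes
    # column j; start the global weight (lambda1 times that) midway
    ctz_max <- apply(crossprod(C, Z), 2, max)
    lambda3 <- max(lambda1, 1e-8) *
      max(stats::median(pmax(ctz_max, 0)) * 2 / alpha, 1e-8) / 2
    adapt <- TRUE
  } else {
    lambda3 <- config$lambda3
    adapt <- FALSE
  }

  trace <- list()
  obj_prev <- Inf
  iter <- 0L
  converged <- FALSE
  round_idx <- 0L
  max_rounds <- 12L
  round_budget <- 20L
  frozen <- !adapt
  post_halvings <- 6L   # frac re-checks after the frozen run converges

  while (iter < config$max_iter) {
    round_idx <- round_idx + 1L
    round_iters <- if (frozen) config$max_iter - iter else
      min(round_budget, config$max_iter - iter)
    round_conv <- FALSE
    for (it in seq_len(round_iters)) {
      iter <- iter + 1L
      B <- update_b(D, Z, lambda2)
      obj_b <- plier_objective(D, C, Z, U, B, lambda1, lambda2, lambda3)
      # clipping the unconstrained Z solution can climb; an exact line search
      # toward the clipped candidate keeps every iteration a descent step
      # while staying inside the non-negative cone
      Zc <- update_z(D, B, C, U, lambda1)
      dZ <- Zc - Z
      aa <- sum((dZ %*% B)^2) + lambda1 * sum(dZ^2)
      bb <- -2 * sum((D - Z %*% B) * (dZ %*% B)) +
        2 * lambda1 * sum((Z - C %*% U) * dZ)
      step <- if (aa > 0) min(1, max(0, -bb / (2 * aa))) else 1
      Z <- Z + step * dZ
      if (lambda1 > 0) {
        # the U-dependent global terms are lambda1||Z-CU||^2 + lambda3 pen(U);
        # dividing by lambda1 gives the unit-weight subproblem update_u solves
        U <- update_u(Z, C, lambda3 / lambda1, alpha, config$max_path, U_init = U)
      }
      obj <- plier_objective(D, C, Z, U, B, lambda1, lambda2, lambda3)
      if (!is.finite(obj)) abort(sprintf("objective became non-finite at iteration %d.", iter))
      # the solver's own objective: elastic-net U penalty instead of pure L1
      pen_u <- lambda3 * (alpha * sum(abs(U)) + (1 - alpha) / 2 * sum(U^2))
      obj_int <- sum(attr(obj, "terms")[c("recon", "prior", "b_ridge")]) + pen_u
      trace[[iter]] <- tibble(iteration = iter, objective = as.numeric(obj),
                              solver_objective = obj_int,
                              after_b = as.numeric(obj_b),
                              recon = attr(obj, "terms")[["recon"]],
                              prior = attr(obj, "terms")[["prior"]],
                              b_ridge = attr(obj, "terms")[["b_ridge"]],
                              u_l1 = attr(obj, "terms")[["u_l1"]],
                              lambda3 = lambda3)
      if (verbose) cat(sprintf("iter %3d  obj %.6g  lambda3 %.4g\n", iter, obj, lambda3))
      rel <- if (is.finite(obj_prev)) abs(obj_int - obj_prev) / max(obj_prev, 1e-12) else Inf
      obj_prev <- obj_int
      if (rel < config$tol) { round_conv <- TRUE; break }
    }

    frac_now <- mean(colSums(U > 0) >= 1)
    if (frozen) {
      converged <- round_conv
      # a frozen lambda3 chosen by the search must still deliver the frac
      # target at convergence; if support decayed, keep relaxing lambda3
      if (adapt && round_conv && frac_now < config$frac &&
          post_halvings > 0L && iter < config$max_iter) {
        post_halvings <- post_halvings - 1L
        lambda3 <- lambda3 / 2
        converged <- FALSE
        obj_prev <- Inf
        next
      }
      break
    }
    if (frac_now >= config$frac || round_idx >= max_rounds) {
      # target met (or search budget spent): freeze and run to convergence
      frozen <- TRUE
      obj_prev <- Inf
    } else {
      lambda3 <- lambda3 / 2
    }
  }

  trace <- dplyr::bind_rows(trace)
  dimnames(Z) <- list(rownames(D), paste0("LV", seq_len(k)))
  dimnames(U) <- list(colnames(C), colnames(Z))
  dimnames(B) <- list(colnames(Z), colnames(D))
  structure(
    list(Z = Z, U = U, B = B, set_names = colnames(C),
         lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
         config = config, trace = trace, converged = converged,
         iterations = iter, row_center = row_center, row_scale = row_scale,
         frac_achieved = mean(colSums(U > 0) >= 1),
         version = "methlv-model-1"),
    class = "meth_plier"
  )
}

#' @export
print.meth_plier <- function(x, ...) {
  cat("<meth_plier> ", nrow(x$Z), " features x ", ncol(x$Z), " LVs, ",
      ncol(x$B), " samples\n", sep = "")
  cat(sprintf("  lambda1=%.4g lambda2=%.4g lambda3=%.4g  iterations=%d  converged=%s\n",
              x$lambda1, x$lambda2, x$lambda3, x$iterations, x$converged))
  cat(sprintf("  LVs with >=1 gene-set association: %.0f%%\n", 100 * x$frac_achieved))
  invisible(x)
}

#' Tidy the gene-set associations of a fitted model
#'
#' One row per nonzero entry of `U`: which gene set loads on which latent
#' variable and with what weight.
#'
#' @param x a `meth_plier` model.
#' @param ... unused.
#' @export
tidy.meth_plier <- function(x, ...) {
  idx <- which(x$U > 0, arr.ind = TRUE)
  out <- tibble(gene_set = rownames(x$U)[idx[, 1]],
                lv = colnames(x$U)[idx[, 2]],
                weight = x$U[idx])
  dplyr::arrange(out, .data$lv, dplyr::desc(.data$weight))
}

#' @export
glance.meth_plier <- function(x, ...) {
  tibble(k = ncol(x$Z), n_features = nrow(x$Z), n_samples = ncol(x$B),
         n_sets = nrow(x$U), iterations = x$iterations,
         converged = x$converged,
         objective = utils::tail(x$trace$objective, 1),
         frac_prior_associated = x$frac_achieved,
         lambda1 = x$lambda1, lambda2 = x$lambda2, lambda3 = x$lambda3)
}
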