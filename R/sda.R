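# Sparse Bayesian tensor decomposition fitted by mean-field variational
# inference (coordinate ascent). The model is
#   Y[n,l,t] = sum_c A[n,c] * B[t,c] * X[c,l] + eps[n,l,t],
#   eps ~ N(0, 1/lambda[l,t]),
# observed only where the individual x condition mask is 1. Gene loadings
# carry a spike-and-slab prior, X[c,l] = s[c,l] * w[c,l] with
# s ~ Bernoulli(pi_c), w ~ N(0, 1/beta_c), pi_c ~ Beta, beta_c ~ Gamma,
# which shrinks loadings of uninvolved genes exactly toward zero and yields
# a posterior inclusion probability (PIP) per gene and component.
#
# The variational family factorizes as
#   q(A) q(B) q(s, w) q(lambda) q(pi) q(beta),
# with q(w | s = 0) tied to the prior at the current E[beta] so that spike
# terms cancel cleanly in the evidence lower bound (ELBO). One sweep updates,
# in this fixed order: lambda, the slab/spike of X (per component), A (per
# component), B (per component), then the component inclusion rates pi and
# slab precisions beta. Every update is an exact coordinate maximizer, so the
# ELBO is non-decreasing across sweeps up to floating-point tolerance.

#' Hyperparameters of the decomposition priors
#'
#' @param noise_shape,noise_rate Gamma prior on each noise precision
#'   lambda_lt.
#' @param slab_shape,slab_rate Gamma prior on each component's slab precision.
#' @param sparsity_a,sparsity_b Beta prior on each component's inclusion
#'   probability.
#' @param a_prior_scale,b_prior_scale Prior variances of the individual-score
#'   and condition-score entries.
#' @return A `sda_hyper` list.
#' @export
sda_hyper <- function(noise_shape = 1e-3, noise_rate = 1e-3,
                      slab_shape = 1e-3, slab_rate = 1e-3,
                      sparsity_a = 1, sparsity_b = 1,
                      a_prior_scale = 1, b_prior_scale = 1) {
  h <- list(noise_shape = noise_shape, noise_rate = noise_rate,
            slab_shape = slab_shape, slab_rate = slab_rate,
            sparsity_a = sparsity_a, sparsity_b = sparsity_b,
            a_prior_scale = a_prior_scale, b_prior_scale = b_prior_scale)
  if (any(unlist(h) <= 0)) {
    stop("all hyperparameters must be strictly positive", call. = FALSE)
  }
  structure(h, class = "sda_hyper")
}

PREC_MIN <- 1e-8
PREC_MAX <- 1e8
PIP_MIN <- 1e-10

#' Fit the sparse tensor decomposition by variational inference
#'
#' Decomposes an individuals x genes x conditions tensor into `n_components`
#' latent components, each defined by individual scores (a column of A),
#' condition activity scores (a column of B) and gene loadings (a row of X)
#' under a spike-and-slab sparsity prior. Entries masked as unobserved
#' contribute to no update. The ELBO is evaluated after every sweep and is
#' non-decreasing; fitting stops when its relative change falls below `tol`
#' or after `max_iter` sweeps.
#'
#' @param tensor An [expression_tensor()].
#' @param n_components Number of components C (1..500).
#' @param hyper An [sda_hyper()]; defaults are vague.
#' @param max_iter Maximum coordinate-ascent sweeps.
#' @param tol Relative ELBO change declaring convergence.
#' @param seed Integer seed for the initialization.
#' @param init `"svd"` (default: slab means and individual scores from a
#'   truncated SVD of the condition-averaged matrix) or `"random"` (seeded
#'   N(0,1) scores). Coordinate ascent cannot resurrect a component whose
#'   scores decay to zero, so a data-scaled start that captures every signal
#'   direction matters; see the vignette.
#' @param warmup Number of initial sweeps during which the component
#'   inclusion rates stay at their prior (see Details in the vignette).
#' @return An `sda_fit` object with posterior-mean matrices `A` (N x C),
#'   `B` (T x C), `X_mean` (C x L, already spike-weighted), `pip` (C x L),
#'   `lambda_mean` (L x T), the `elbo_trace`, a `converged` flag, and the
#'   variational parameters in `vb` for downstream use.
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 40, n_genes = 60, n_tissues = 2,
#'                   n_sparse_components = 1, n_dense_components = 0,
#'                   genes_per_sparse_component = 8, seed = 3)
#' tt <- simulate_truth(cfg)
#' y <- assemble_tensor(tt, seed = 3)
#' fit <- fit_sda(y, n_components = 2, max_iter = 30, seed = 3)
#' fit$converged
fit_sda <- function(tensor, n_components, hyper = sda_hyper(),
                    max_iter = 200L, tol = 1e-6, seed = 1L,
                    init = c("svd", "random"), warmup = 10L) {
  stopifnot(inherits(tensor, "expression_tensor"),
            inherits(hyper, "sda_hyper"))
  C <- assert_count(n_components, "n_components")
  if (C > 500L) stop("`n_components` is capped at 500", call. = FALSE)
  max_iter <- assert_count(max_iter, "max_iter")
  init <- match.arg(init)
  d <- dim(tensor$values)
  N <- d[1]; L <- d[2]; Tt <- d[3]
  Y <- tensor$values
  mask <- tensor$mask
  obs <- lapply(seq_len(Tt), function(t) which(mask[, t] == 1L))
  n_t <- vapply(obs, length, integer(1))
  # masked slices must never influence the fit: zero them out up front
  for (t in seq_len(Tt)) {
    off <- which(mask[, t] == 0L)
    if (length(off)) Y[off, , t] <- 0
  }

  h <- hyper
  st <- with_seed(derive_seed(seed, 5L), {
    Am <- matrix(stats::rnorm(N * C), N, C)
    Bm <- matrix(stats::rnorm(Tt * C), Tt, C)
    W <- matrix(0, C, L)
    if (init == "svd") {
      Ybar <- matrix(0, N, L)
      wsum <- pmax(rowSums(mask), 1)
      for (t in seq_len(Tt)) Ybar <- Ybar + Y[, , t]
      Ybar <- Ybar / wsum
      k <- min(C, N - 1L, L - 1L)
      sv <- svd(Ybar, nu = k, nv = k)
      Am[, seq_len(k)] <- sv$u %*% diag(sqrt(sv$d[seq_len(k)]), k)
      W[seq_len(k), ] <- diag(sqrt(sv$d[seq_len(k)]), k) %*% t(sv$v)
      Bm <- matrix(1, Tt, C)
    }
    list(Am = Am, Bm = Bm, W = W)
  })
  Am <- st$Am; Bm <- st$Bm; W <- st$W
  # small initial variances and near-slab PIPs: unit-scale initial variances
  # inflate every ridge denominator at the cold start and, together with the
  # spike weighting, drive all means multiplicatively toward the spurious
  # all-zero fixed point before any signal is captured
  Av <- matrix(1e-6, N, C); Bv <- matrix(1e-6, Tt, C)
  Wv <- matrix(1e-6, C, L)
  G <- matrix(1 - 1e-3, C, L)
  EX <- G * W
  EX2 <- G * (W^2 + Wv)
  lu <- matrix(h$noise_shape, L, Tt); lv <- matrix(h$noise_rate, L, Tt)
  El <- clip(lu / lv, PREC_MIN, PREC_MAX)
  pa <- rep(h$sparsity_a, C); pb <- rep(h$sparsity_b, C)
  ba <- rep(h$slab_shape, C); bb <- rep(h$slab_rate, C)
  Eb <- clip(ba / bb, PREC_MIN, PREC_MAX)

  fitted_t <- function() {
    lapply(seq_len(Tt), function(t) Am %*% (Bm[t, ] * EX))
  }
  Fs <- fitted_t()

  elbo_trace <- numeric(0)
  converged <- FALSE
  monotone <- TRUE
  prev <- -Inf

  for (it in seq_len(max_iter)) {
    EA2 <- Am^2 + Av
    EB2 <- Bm^2 + Bv

    ## -- lambda (noise precisions), per gene x condition ------------------
    S2 <- matrix(0, L, Tt)
    for (t in seq_len(Tt)) {
      o <- obs[[t]]
      R <- Y[o, , t, drop = FALSE]
      dim(R) <- c(length(o), L)
      R <- R - Fs[[t]][o, , drop = FALSE]
      corr <- EA2[o, , drop = FALSE] %*% (EB2[t, ] * EX2) -
        (Am[o, , drop = FALSE]^2) %*% (Bm[t, ]^2 * EX^2)
      S2[, t] <- colSums(R^2) + colSums(corr)
    }
    lu <- matrix(h$noise_shape + n_t / 2, L, Tt, byrow = TRUE)
    lv <- h$noise_rate + S2 / 2
    El <- clip(lu / lv, PREC_MIN, PREC_MAX)

    ## -- X spike-and-slab, per component ----------------------------------
    SA2 <- crossprod(mask, EA2)                  # T x C: sum of E[A^2] over obs
    for (c in seq_len(C)) {
      coef <- EB2[, c] * SA2[, c]
      rho <- as.vector(El %*% coef)              # length L
      b <- numeric(L)
      for (t in seq_len(Tt)) {
        o <- obs[[t]]
        Rc <- Y[o, , t, drop = FALSE]
        dim(Rc) <- c(length(o), L)
        Rc <- Rc - Fs[[t]][o, , drop = FALSE] +
          tcrossprod(Am[o, c] * Bm[t, c], EX[c, ])
        b <- b + Bm[t, c] * (El[, t] * as.vector(crossprod(Rc, Am[o, c])))
      }
      Wv[c, ] <- 1 / (Eb[c] + rho)
      W[c, ] <- Wv[c, ] * b
      # q(w | s = 1) above is the exact conditional update whatever q(s) is;
      # q(s) itself is frozen at 0.5 during warm-up so the spike cannot
      # extinguish components before their loadings align with signal
      if (it > warmup) {
        logit <- digamma(pa[c]) - digamma(pb[c]) +
          0.5 * (log(Eb[c]) - log(Eb[c] + rho)) + 0.5 * b^2 / (Eb[c] + rho)
        G[c, ] <- clip(stats::plogis(logit), PIP_MIN, 1 - PIP_MIN)
      }
      newEX <- G[c, ] * W[c, ]
      for (t in seq_len(Tt)) {
        Fs[[t]] <- Fs[[t]] + tcrossprod(Am[, c] * Bm[t, c], newEX - EX[c, ])
      }
      EX[c, ] <- newEX
      EX2[c, ] <- G[c, ] * (W[c, ]^2 + Wv[c, ])
    }

    ## -- A (individual scores), per component -----------------------------
    xe <- EX2 %*% El                             # C x T
    for (c in seq_len(C)) {
      prec <- 1 / h$a_prior_scale +
        as.vector(mask %*% (EB2[, c] * xe[c, ]))
      b <- numeric(N)
      for (t in seq_len(Tt)) {
        o <- obs[[t]]
        Rc <- Y[o, , t, drop = FALSE]
        dim(Rc) <- c(length(o), L)
        Rc <- Rc - Fs[[t]][o, , drop = FALSE] +
          tcrossprod(Am[o, c] * Bm[t, c], EX[c, ])
        b[o] <- b[o] + Bm[t, c] * as.vector(Rc %*% (El[, t] * EX[c, ]))
      }
      Av[, c] <- 1 / prec
      newA <- b / prec
      for (t in seq_len(Tt)) {
        Fs[[t]] <- Fs[[t]] + tcrossprod((newA - Am[, c]) * Bm[t, c], EX[c, ])
      }
      Am[, c] <- newA
    }
    EA2 <- Am^2 + Av
    SA2 <- crossprod(mask, EA2)

    ## -- B (condition scores), per component ------------------------------
    for (c in seq_len(C)) {
      for (t in seq_len(Tt)) {
        o <- obs[[t]]
        prec <- 1 / h$b_prior_scale + SA2[t, c] * xe[c, t]
        Rc <- Y[o, , t, drop = FALSE]
        dim(Rc) <- c(length(o), L)
        Rc <- Rc - Fs[[t]][o, , drop = FALSE] +
          tcrossprod(Am[o, c] * Bm[t, c], EX[c, ])
        b <- sum(Am[o, c] * as.vector(Rc %*% (El[, t] * EX[c, ])))
        Bv[t, c] <- 1 / prec
        newB <- b / prec
        Fs[[t]] <- Fs[[t]] + tcrossprod(Am[, c] * (newB - Bm[t, c]), EX[c, ])
        Bm[t, c] <- newB
      }
    }

    ## -- inclusion rates and slab precisions ------------------------------
    # the inclusion-rate update is held at its prior for the first `warmup`
    # sweeps: updating it from a cold start drives all PIPs to the spike
    # before the loadings can lock onto signal (skipping a coordinate update
    # cannot decrease the ELBO)
    if (it > warmup) {
      gs <- rowSums(G)
      pa <- h$sparsity_a + gs
      pb <- h$sparsity_b + L - gs
    }
    Ew2 <- G * (W^2 + Wv) + (1 - G) / Eb        # E[w^2] incl. tied spike slab
    ba <- h$slab_shape + L / 2
    bb <- h$slab_rate + rowSums(Ew2) / 2
    Eb <- clip(ba / bb, PREC_MIN, PREC_MAX)

    ## -- ELBO --------------------------------------------------------------
    e <- sda_elbo_internal(Y, obs, n_t, Fs, Am, Av, Bm, Bv, W, Wv, G,
                           lu, lv, pa, pb, ba, bb, Eb, h)
    if (length(elbo_trace) && e < prev - 1e-8 * abs(prev)) monotone <- FALSE
    elbo_trace <- c(elbo_trace, e)
    if (is.finite(prev) && it > warmup + 1L &&
        abs(e - prev) <= tol * (abs(prev) + .Machine$double.eps)) {
      converged <- TRUE
      prev <- e
      break
    }
    prev <- e
  }

  # components whose loadings collapse entirely into the spike: their
  # inclusion indicators no longer affect the likelihood, so q(s) freezes at
  # an arbitrary value; report the inclusion probability of an identically
  # zero loading row as (numerically) zero and flag the component as pruned
  pruned <- apply(abs(G * W), 1, max) < 1e-8
  G[pruned, ] <- PIP_MIN

  structure(list(
    A = Am, A_var = Av, B = Bm, B_var = Bv,
    X_mean = G * W, slab_mean = W, slab_var = Wv, pip = G, pruned = pruned,
    lambda_mean = clip(lu / lv, PREC_MIN, PREC_MAX),
    inclusion_rate = pa / (pa + pb),
    slab_precision = Eb,
    elbo_trace = elbo_trace, converged = converged, monotone = monotone,
    n_iter = length(elbo_trace), seed = seed, hyper = h,
    .lu = lu, .lv = lv, .pa = pa, .pb = pb, .ba = ba, .bb = bb,
    individual_ids = tensor$individual_ids, gene_ids = tensor$gene_ids,
    tissue_labels = tensor$tissue_labels
  ), class = "sda_fit")
}

# Full evidence lower bound for the current variational parameters.
sda_elbo_internal <- function(Y, obs, n_t, Fs, Am, Av, Bm, Bv, W, Wv, G,
                              lu, lv, pa, pb, ba, bb, Eb, h) {
  Tt <- length(obs); L <- nrow(lu); C <- nrow(W)
  El <- clip(lu / lv, PREC_MIN, PREC_MAX)
  Ell <- digamma(lu) - log(lv)
  EA2 <- Am^2 + Av
  EB2 <- Bm^2 + Bv
  EX <- G * W
  EX2 <- G * (W^2 + Wv)
  lik <- 0
  for (t in seq_len(Tt)) {
    o <- obs[[t]]
    R <- Y[o, , t, drop = FALSE]
    dim(R) <- c(length(o), L)
    R <- R - Fs[[t]][o, , drop = FALSE]
    corr <- EA2[o, , drop = FALSE] %*% (EB2[t, ] * EX2) -
      (Am[o, , drop = FALSE]^2) %*% (Bm[t, ]^2 * EX^2)
    S2col <- colSums(R^2) + colSums(corr)
    lik <- lik + 0.5 * n_t[t] * sum(Ell[, t] - log(2 * pi)) -
      0.5 * sum(El[, t] * S2col)
  }
  kl_norm <- function(m, v, s2) {
    0.5 * sum((v + m^2) / s2 - 1 - log(v / s2))
  }
  kl_gamma <- function(a, bta, a0, b0) {
    sum((a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
          a0 * (log(bta) - log(b0)) + a * (b0 - bta) / bta)
  }
  kl_beta <- function(a, bta, a0, b0) {
    sum(lbeta(a0, b0) - lbeta(a, bta) +
          (a - a0) * digamma(a) + (bta - b0) * digamma(bta) +
          (a0 - a + b0 - bta) * digamma(a + bta))
  }
  kl <- kl_norm(Am, Av, h$a_prior_scale) + kl_norm(Bm, Bv, h$b_prior_scale) +
    kl_gamma(lu, lv, h$noise_shape, h$noise_rate) +
    kl_gamma(ba, bb, h$slab_shape, h$slab_rate) +
    kl_beta(pa, pb, h$sparsity_a, h$sparsity_b)
  # spike-and-slab term for X
  Elogpi <- digamma(pa) - digamma(pa + pb)
  Elog1mpi <- digamma(pb) - digamma(pa + pb)
  Elogb <- digamma(ba) - log(bb)
  x_term <- 0
  for (c in seq_len(C)) {
    g <- G[c, ]
    s1 <- 0.5 * Elogb[c] - 0.5 * Eb[c] * (W[c, ]^2 + Wv[c, ]) +
      0.5 * log(Wv[c, ]) + 0.5
    s0 <- 0.5 * Elogb[c] - 0.5 * log(Eb[c])
    ent <- -(g * log(g) + (1 - g) * log(1 - g))
    x_term <- x_term + sum(g * (s1 + Elogpi[c]) +
                             (1 - g) * (s0 + Elog1mpi[c]) + ent)
  }
  lik - kl + x_term
}

#' Posterior-mean reconstruction of the tensor
#'
#' Returns `sum_c A[n, c] * B[t, c] * Xhat[c, l]` with `Xhat` the
#' spike-weighted posterior-mean loadings (`pip * slab mean`).
#'
#' @param fit An `sda_fit` (or any list with `A`, `B`, `X_mean`).
#' @return A numeric N x L x T array.
#' @export
reconstruct <- function(fit) {
  A <- fit$A; B <- fit$B; X <- fit$X_mean
  N <- nrow(A); Tt <- nrow(B); L <- ncol(X)
  out <- array(0, dim = c(N, L, Tt))
  for (t in seq_len(Tt)) out[, , t] <- A %*% (B[t, ] * X)
  out
}

#' Evidence lower bound of a fitted decomposition
#'
#' Recomputes the ELBO of the stored variational posterior against a tensor.
#' Entries masked as unobserved contribute nothing, so perturbing them leaves
#' the value unchanged.
#'
#' @param fit An `sda_fit`.
#' @param tensor The `expression_tensor` the fit refers to.
#' @return A finite scalar.
#' @export
elbo <- function(fit, tensor) {
  stopifnot(inherits(fit, "sda_fit"), inherits(tensor, "expression_tensor"))
  d <- dim(tensor$values)
  Tt <- d[3]
  Y <- tensor$values
  mask <- tensor$mask
  obs <- lapply(seq_len(Tt), function(t) which(mask[, t] == 1L))
  n_t <- vapply(obs, length, integer(1))
  for (t in seq_len(Tt)) {
    off <- which(mask[, t] == 0L)
    if (length(off)) Y[off, , t] <- 0
  }
  EX <- fit$pip * fit$slab_mean
  Fs <- lapply(seq_len(Tt), function(t) fit$A %*% (fit$B[t, ] * EX))
  h <- fit$hyper
  # the exact variational parameters stored by fit_sda, with fallbacks
  # reconstructed from posterior summaries for hand-built decompositions
  lu <- fit$.lu %||% matrix(h$noise_shape + rep(n_t, each = d[2]) / 2,
                            d[2], Tt)
  lv <- fit$.lv %||% (lu / fit$lambda_mean)
  pa <- fit$.pa %||% (h$sparsity_a + rowSums(fit$pip))
  pb <- fit$.pb %||% (h$sparsity_b + ncol(fit$pip) - rowSums(fit$pip))
  ba <- fit$.ba %||% rep(h$slab_shape + ncol(fit$pip) / 2, nrow(fit$pip))
  bb <- fit$.bb %||% (ba / fit$slab_precision)
  sda_elbo_internal(Y, obs, n_t, Fs, fit$A, fit$A_var, fit$B, fit$B_var,
                    fit$slab_mean, fit$slab_var, fit$pip, lu, lv, pa, pb,
                    ba, bb, fit$slab_precision, h)
}

#' Resolve scale and sign indeterminacy of a decomposition
#'
#' Rescales each component's posterior-mean loading row to unit L2 norm,
#' absorbing the scale into the corresponding column of A, and flips signs so
#' the largest-magnitude gene loading of each component is positive. The
#' posterior-mean reconstruction is unchanged.
#'
#' @param fit An `sda_fit`.
#' @return The modified `sda_fit`; components with a zero-norm loading row
#'   are left unchanged and listed in attribute `"zero_norm_components"`.
#' @export
orient_and_scale <- function(fit) {
  stopifnot(inherits(fit, "sda_fit"))
  X <- fit$X_mean
  C <- nrow(X)
  zero <- integer(0)
  for (c in seq_len(C)) {
    nrm <- sqrt(sum(X[c, ]^2))
    if (nrm == 0) {
      zero <- c(zero, c)
      next
    }
    sgn <- sign(X[c, which.max(abs(X[c, ]))])
    if (sgn == 0) sgn <- 1
    fac <- sgn / nrm
    X[c, ] <- X[c, ] * fac
    fit$slab_mean[c, ] <- fit$slab_mean[c, ] * fac
    fit$slab_var[c, ] <- fit$slab_var[c, ] * fac^2
    fit$A[, c] <- fit$A[, c] / fac
    fit$A_var[, c] <- fit$A_var[, c] / fac^2
  }
  fit$X_mean <- X
  attr(fit, "zero_norm_components") <- zero
  fit
}

#' @export
print.sda_fit <- function(x, ...) {
  cat(sprintf(
    "<sda_fit> %d x %d x %d tensor, %d components, %d sweeps (%s)\n",
    nrow(x$A), ncol(x$X_mean), nrow(x$B), ncol(x$A), x$n_iter,
    if (x$converged) "converged" else "max_iter reached"))
  cat(sprintf("  final ELBO %.4f\n", x$elbo_trace[length(x$elbo_trace)]))
  invisible(x)
}
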