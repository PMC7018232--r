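# Mendelian-randomization mediation: does a trans-eSNP transmit its effect
# on a component (or trans-eGene) through its cis gene? Implemented as
# single-instrument two-stage least squares: the SNP instruments the cis
# gene, and the mediated effect beta_M is the 2SLS slope of the outcome on
# the instrumented cis expression — algebraically the ratio
# cov(outcome, dosage) / cov(cis, dosage).

#' Single-instrument Mendelian-randomization mediation
#'
#' Stage 1 regresses cis expression on the SNP dosage; stage 2 regresses the
#' outcome on the stage-1 fitted values. The mediated-effect estimate
#' `beta_M` equals the ratio `cov(outcome, dosage) / cov(cis, dosage)`; its
#' standard error uses the 2SLS residuals (outcome minus `beta_M` times the
#' *observed* cis expression). The first-stage F statistic is reported and
#' instruments with F < 10 are flagged as weak.
#'
#' Interpretation requires the exclusion restriction: a direct (pleiotropic)
#' SNP effect `delta` on the outcome inflates `beta_M` by `delta / alpha`
#' (see [simulate_mediation_triple()]), which no single-instrument analysis
#' can detect.
#'
#' @param dosage Numeric dosage vector (polymorphic).
#' @param cis_expr Cis-gene expression vector.
#' @param outcome Outcome vector (component individual scores or trans-gene
#'   expression).
#' @param snp_id,mediator_gene,outcome_id Optional identifiers carried into
#'   the result.
#' @return A one-row tibble with `snp_id`, `mediator_gene`, `outcome_id`,
#'   `beta_M`, `se`, `t`, `p`, `instrument_F`, `weak_instrument`.
#' @export
#' @examples
#' tr <- simulate_mediation_triple(500, 0.3, alpha = 1, gamma = 0.8, seed = 1)
#' mr_mediation(tr$dosage, tr$cis, tr$outcome)
mr_mediation <- function(dosage, cis_expr, outcome, snp_id = NA_character_,
                         mediator_gene = NA_character_,
                         outcome_id = NA_character_) {
  n <- length(dosage)
  if (length(cis_expr) != n || length(outcome) != n) {
    stop("dosage, cis_expr and outcome must have equal length", call. = FALSE)
  }
  if (n < 30) stop("mediation requires n >= 30", call. = FALSE)
  if (stats::var(dosage) == 0) {
    stop("dosage is monomorphic; not a usable instrument", call. = FALSE)
  }
  # stage 1: cis ~ dosage
  s1 <- stats::lm.fit(cbind(1, dosage), cis_expr)
  chat <- s1$fitted.values
  f_stat <- {
    r2 <- 1 - sum(s1$residuals^2) / sum((cis_expr - mean(cis_expr))^2)
    (n - 2) * r2 / (1 - r2)
  }
  # stage 2 on instrumented cis; slope equals the covariance ratio
  vchat <- sum((chat - mean(chat))^2)
  beta_m <- sum((chat - mean(chat)) * outcome) / vchat
  a0 <- mean(outcome) - beta_m * mean(cis_expr)
  resid2sls <- outcome - a0 - beta_m * cis_expr
  sigma2 <- sum(resid2sls^2) / (n - 2)
  se <- sqrt(sigma2 / vchat)
  tstat <- beta_m / se
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  tibble::tibble(snp_id = snp_id, mediator_gene = mediator_gene,
                 outcome_id = outcome_id, beta_M = beta_m, se = se,
                 t = tstat, p = p, instrument_F = f_stat,
                 weak_instrument = f_stat < 10)
}

resolve_pairs <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  need <- c("snp_id", "cis_gene", "outcome")
  if (!all(need %in% names(pairs))) {
    stop("`pairs` needs columns snp_id, cis_gene, outcome", call. = FALSE)
  }
  pairs
}

mediate_impl <- function(pairs, get_dosage, get_cis, get_outcome) {
  rows <- purrr::pmap(pairs[c("snp_id", "cis_gene", "outcome")],
                      function(snp_id, cis_gene, outcome) {
    err <- function(msg) {
      tibble::tibble(snp_id = snp_id, mediator_gene = cis_gene,
                     outcome_id = as.character(outcome), beta_M = NA_real_,
                     se = NA_real_, t = NA_real_, p = NA_real_,
                     instrument_F = NA_real_, weak_instrument = NA,
                     error = msg)
    }
    d <- get_dosage(snp_id)
    if (is.null(d)) return(err("unknown SNP id"))
    cx <- get_cis(cis_gene)
    if (is.null(cx)) return(err("unknown cis gene"))
    out <- get_outcome(outcome, cis_gene)
    if (is.character(out)) return(err(out))
    res <- mr_mediation(d, cx, out, snp_id = snp_id,
                        mediator_gene = cis_gene,
                        outcome_id = as.character(outcome))
    res$error <- NA_character_
    res
  })
  if (!length(rows)) {
    return(tibble::tibble(
      snp_id = character(), mediator_gene = character(),
      outcome_id = character(), beta_M = numeric(), se = numeric(),
      t = numeric(), p = numeric(), instrument_F = numeric(),
      weak_instrument = logical(), error = character(), q = numeric()))
  }
  out <- dplyr::bind_rows(rows)
  ok <- is.na(out$error)
  out$q <- NA_real_
  if (any(ok)) out$q[ok] <- bh_fdr(out$p[ok])
  out
}

#' Mediation of component individual scores through cis genes
#'
#' Applies [mr_mediation()] to each (SNP, cis gene, component) triple with
#' the component's individual scores as outcome; BH q-values are appended
#' across pairs. Unresolvable ids yield per-pair error records and the run
#' continues.
#'
#' @param fit An `sda_fit` (its `A` columns are the outcomes).
#' @param genotypes A `genotype_data`.
#' @param cis_expression Genes x individuals matrix with gene row names.
#' @param pairs Data frame with columns `snp_id`, `cis_gene`, `outcome`
#'   (component index or id).
#' @return A `mediation_result` tibble, one row per pair.
#' @export
mediate_component <- function(fit, genotypes, cis_expression, pairs) {
  pairs <- resolve_pairs(pairs)
  cis_expression <- as.matrix(cis_expression)
  comp_ids <- as.character(seq_len(ncol(fit$A)))
  out <- mediate_impl(
    pairs,
    get_dosage = function(s) {
      j <- match(s, genotypes$snps$snp_id)
      if (is.na(j)) NULL else genotypes$dosages[, j]
    },
    get_cis = function(g) {
      i <- match(g, rownames(cis_expression))
      if (is.na(i)) NULL else cis_expression[i, ]
    },
    get_outcome = function(o, cis_gene) {
      j <- match(as.character(o), comp_ids)
      if (is.na(j)) "unknown component id" else fit$A[, j]
    }
  )
  class(out) <- c("mediation_result", class(out))
  out
}

#' Mediation of individual trans-gene expression through cis genes
#'
#' As [mediate_component()], with the expression of each trans-eGene as the
#' outcome. Pairs whose trans gene equals the cis gene are rejected as
#' degenerate self-mediation.
#'
#' @param expression Genes x individuals matrix with gene row names
#'   (provides both cis and trans genes).
#' @param genotypes A `genotype_data`.
#' @param pairs Data frame with columns `snp_id`, `cis_gene`, `outcome`
#'   (the trans gene id).
#' @return A `mediation_result` tibble.
#' @export
mediate_genes <- function(expression, genotypes, pairs) {
  pairs <- resolve_pairs(pairs)
  expression <- as.matrix(expression)
  out <- mediate_impl(
    pairs,
    get_dosage = function(s) {
      j <- match(s, genotypes$snps$snp_id)
      if (is.na(j)) NULL else genotypes$dosages[, j]
    },
    get_cis = function(g) {
      i <- match(g, rownames(expression))
      if (is.na(i)) NULL else expression[i, ]
    },
    get_outcome = function(o, cis_gene) {
      if (identical(as.character(o), as.character(cis_gene))) {
        return("self-mediation pair rejected")
      }
      i <- match(as.character(o), rownames(expression))
      if (is.na(i)) "unknown trans gene id" else expression[i, ]
    }
  )
  class(out) <- c("mediation_result", class(out))
  out
}
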