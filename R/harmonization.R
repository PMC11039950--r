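STRAND_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs read the same on both strands, so their orientation
#' cannot be resolved from alleles alone.
#'
#' @param effect_allele,other_allele Single-base allele vectors.
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  unname(STRAND_COMPLEMENT[toupper(effect_allele)] == toupper(other_allele))
}

# Vectorized allele-orientation resolution between an exposure record and an
# outcome record for the same variant.  Returns the action taken and whether
# the outcome effect must be sign-flipped:
#   identical orientation            -> kept
#   swapped alleles                  -> flipped (outcome beta * -1, eaf -> 1-eaf)
#   strand complement of either case -> as above (dropped in strict mode)
#   palindromic pair                 -> dropped_palindromic (always; no EAF rescue)
#   anything else                    -> dropped_incompatible
resolve_orientation <- function(ea_x, oa_x, ea_y, oa_y, strict = FALSE) {
  n <- length(ea_x)
  action <- rep("dropped_incompatible", n)
  flip <- rep(FALSE, n)

  pal <- is_palindromic(ea_x, oa_x)
  same <- ea_y == ea_x & oa_y == oa_x
  swap <- ea_y == oa_x & oa_y == ea_x
  cea <- unname(STRAND_COMPLEMENT[ea_y])
  coa <- unname(STRAND_COMPLEMENT[oa_y])
  comp_same <- cea == ea_x & coa == oa_x
  comp_swap <- cea == oa_x & coa == ea_x

  action[same] <- "kept"
  action[swap] <- "flipped"
  flip[swap] <- TRUE
  if (strict) {
    # strand-ambiguous complements are not rescued in strict mode
    action[!same & !swap & (comp_same | comp_swap)] <- "dropped_incompatible"
  } else {
    action[!same & !swap & comp_same] <- "kept"
    sel <- !same & !swap & !comp_same & comp_swap
    action[sel] <- "flipped"
    flip[sel] <- TRUE
  }
  action[pal] <- "dropped_palindromic"
  flip[pal] <- FALSE
  list(action = action, flip = flip)
}

#' Harmonize one exposure/outcome record pair
#'
#' Aligns the outcome effect to the exposure's effect allele: identical
#' orientation is kept as-is, swapped alleles flip the sign of the outcome
#' beta (and reflect its EAF), strand complements are resolved the same way,
#' palindromic variants are always dropped, and incompatible allele sets are
#' dropped.
#'
#' @param exposure,outcome Single VariantAssociation rows (one-row data
#'   frames as stored in `summary_stats$records`) sharing the same `snp_id`.
#' @param strict If `TRUE`, strand-complement matches are dropped instead of
#'   resolved.
#' @return One-row data frame with columns `snp_id`, `gamma`, `sigma_x`,
#'   `Gamma`, `sigma_y`, `f_stat`, `eaf_exposure`, `eaf_outcome`, `action`.
#'   For dropped records the outcome-side fields are `NA`.
#' @export
harmonize_pair <- function(exposure, outcome, strict = FALSE) {
  if (nrow(exposure) != 1 || nrow(outcome) != 1) {
    stop_usage("harmonize_pair expects single records")
  }
  if (exposure$snp_id != outcome$snp_id) {
    stop_usage(sprintf("snp_id mismatch: '%s' vs '%s'", exposure$snp_id, outcome$snp_id))
  }
  res <- resolve_orientation(exposure$effect_allele, exposure$other_allele,
                             outcome$effect_allele, outcome$other_allele,
                             strict = strict)
  kept <- res$action %in% c("kept", "flipped")
  data.frame(
    snp_id = exposure$snp_id,
    gamma = exposure$beta,
    sigma_x = exposure$se,
    Gamma = if (kept) outcome$beta * ifelse(res$flip, -1, 1) else NA_real_,
    sigma_y = if (kept) outcome$se else NA_real_,
    f_stat = compute_f_statistic(exposure$beta, exposure$se),
    eaf_exposure = exposure$eaf,
    eaf_outcome = if (kept && res$flip) 1 - outcome$eaf else outcome$eaf,
    action = res$action,
    stringsAsFactors = FALSE
  )
}

#' Assemble the analysis-ready harmonized instrument set
#'
#' Joins selected exposure instruments with the outcome summary statistics on
#' `snp_id`, resolves allele orientation per variant ([harmonize_pair]
#' semantics, vectorized), and returns the kept records together with a drop
#' log in which every input instrument is accounted for exactly once.
#'
#' @param exposure_instruments [summary_stats] of already-selected exposure
#'   instruments.
#' @param outcome_stats [summary_stats] for the outcome trait.
#' @param strict Drop strand-complement matches instead of resolving them.
#' @return An object of class `harmonized_set` with fields `exposure_id`,
#'   `outcome_id`, `records` (kept rows: `snp_id`, `gamma`, `sigma_x`,
#'   `Gamma`, `sigma_y`, `f_stat`, `eaf_exposure`, `eaf_outcome`) and
#'   `drop_log` (snp_id, action for every input instrument).
#' @export
build_instrument_set <- function(exposure_instruments, outcome_stats, strict = FALSE) {
  ex <- exposure_instruments$records
  out <- outcome_stats$records
  pair_label <- sprintf("%s -> %s", exposure_instruments$trait_id, outcome_stats$trait_id)
  if (nrow(ex) == 0) {
    mrb_error(sprintf("no instruments supplied for pair %s", pair_label),
              "mrbiome_empty_set_error")
  }
  idx <- match(ex$snp_id, out$snp_id)
  matched <- !is.na(idx)

  action <- rep("dropped_unmatched", nrow(ex))
  flip <- rep(FALSE, nrow(ex))
  if (any(matched)) {
    res <- resolve_orientation(ex$effect_allele[matched], ex$other_allele[matched],
                               out$effect_allele[idx[matched]], out$other_allele[idx[matched]],
                               strict = strict)
    action[matched] <- res$action
    flip[matched] <- res$flip
  }
  kept <- action %in% c("kept", "flipped")
  sign <- ifelse(flip, -1, 1)
  oid <- idx[kept]
  records <- data.frame(
    snp_id = ex$snp_id[kept],
    gamma = ex$beta[kept],
    sigma_x = ex$se[kept],
    Gamma = out$beta[oid] * sign[kept],
    sigma_y = out$se[oid],
    f_stat = compute_f_statistic(ex$beta[kept], ex$se[kept]),
    eaf_exposure = ex$eaf[kept],
    eaf_outcome = ifelse(flip[kept], 1 - out$eaf[oid], out$eaf[oid]),
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  drop_log <- data.frame(snp_id = ex$snp_id, action = action, stringsAsFactors = FALSE)
  if (nrow(records) == 0) {
    mrb_error(sprintf("no harmonizable instruments for pair %s", pair_label),
              "mrbiome_empty_set_error")
  }
  structure(
    list(exposure_id = exposure_instruments$trait_id,
         outcome_id = outcome_stats$trait_id,
         records = records, drop_log = drop_log),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d kept / %d input instruments\n",
              x$exposure_id, x$outcome_id, nrow(x$records), nrow(x$drop_log)))
  tab <- table(x$drop_log$action)
  cat(paste(sprintf("  %s: %d", names(tab), tab), collapse = "\n"), "\n")
  invisible(x)
}

#' Construct a harmonized set directly from aligned effect vectors
#'
#' Convenience constructor for already-aligned per-variant effects, used in
#' simulations and tests where the allele bookkeeping has been done upstream.
#'
#' @param gamma,sigma_x Exposure effects and standard errors (per SD).
#' @param Gamma,sigma_y Outcome effects and standard errors (log odds).
#' @param snp_id Optional variant ids.
#' @param exposure_id,outcome_id Trait labels.
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(gamma, sigma_x, Gamma, sigma_y,
                           snp_id = sprintf("snp%d", seq_along(gamma)),
                           exposure_id = "exposure", outcome_id = "outcome") {
  if (any(sigma_x <= 0) || any(sigma_y <= 0)) stop_usage("standard errors must be > 0")
  records <- data.frame(
    snp_id = as.character(snp_id), gamma = gamma, sigma_x = sigma_x,
    Gamma = Gamma, sigma_y = sigma_y,
    f_stat = (gamma / sigma_x)^2,
    eaf_exposure = rep(NA_real_, length(gamma)),
    eaf_outcome = rep(NA_real_, length(gamma)),
    stringsAsFactors = FALSE
  )
  structure(
    list(exposure_id = exposure_id, outcome_id = outcome_id, records = records,
         drop_log = data.frame(snp_id = records$snp_id,
                               action = rep("kept", nrow(records)),
                               stringsAsFactors = FALSE)),
    class = "harmonized_set"
  )
}

# Subset a harmonized set by record index, keeping the drop log untouched.
subset_set <- function(set, idx) {
  set$records <- set$records[idx, , drop = FALSE]
  rownames(set$records) <- NULL
  set
}
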