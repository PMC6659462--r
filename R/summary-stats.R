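#' Read a GWAS summary-statistic table
#'
#' Reads tab-separated summary statistics with columns `SNP`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n` (names remappable through
#' `col_map`). Rows violating the record invariants (identical alleles,
#' non-positive SE, frequency outside (0,1), unparseable numerics) are
#' rejected with their line numbers and reasons; the read fails outright when
#' more than `max_bad_fraction` of rows are bad.
#'
#' @param path file path.
#' @param col_map named character vector mapping canonical names (snp,
#'   effect_allele, other_allele, eaf, beta, se, pval, n) to file columns.
#' @param max_bad_fraction tolerated fraction of invalid rows.
#' @return data.frame of validated records; rejected rows (with `line` and
#'   `reason`) in attribute `"rejected"`.
#' @export
read_summary_stats <- function(path,
                               col_map = c(snp = "SNP",
                                           effect_allele = "effect_allele",
                                           other_allele = "other_allele",
                                           eaf = "eaf", beta = "beta",
                                           se = "se", pval = "pval", n = "n"),
                               max_bad_fraction = 0.2) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  miss <- setdiff(unname(col_map), names(raw))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  d <- data.frame(
    snp = raw[[col_map[["snp"]]]],
    effect_allele = toupper(raw[[col_map[["effect_allele"]]]]),
    other_allele = toupper(raw[[col_map[["other_allele"]]]]),
    eaf = suppressWarnings(as.numeric(raw[[col_map[["eaf"]]]])),
    beta = suppressWarnings(as.numeric(raw[[col_map[["beta"]]]])),
    se = suppressWarnings(as.numeric(raw[[col_map[["se"]]]])),
    pval = suppressWarnings(as.numeric(raw[[col_map[["pval"]]]])),
    n = suppressWarnings(as.numeric(raw[[col_map[["n"]]]])),
    stringsAsFactors = FALSE
  )
  reason <- rep("", nrow(d))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reason[cond & reason == ""] <<- why
  }
  bad(!d$effect_allele %in% c("A", "C", "G", "T") |
        !d$other_allele %in% c("A", "C", "G", "T"), "invalid allele")
  bad(d$effect_allele == d$other_allele, "identical alleles")
  bad(is.na(d$eaf) | d$eaf <= 0 | d$eaf >= 1, "eaf outside (0,1)")
  bad(is.na(d$beta), "unparseable beta")
  bad(is.na(d$se) | d$se <= 0, "nonpositive SE")
  bad(is.na(d$pval) | d$pval <= 0 | d$pval > 1, "p outside (0,1]")
  keep <- reason == ""
  rejected <- data.frame(line = which(!keep) + 1L,
                         snp = d$snp[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  if (nrow(d) > 0 && nrow(rejected) / nrow(d) > max_bad_fraction) {
    stop(sprintf("%d of %d rows invalid (first: line %d, %s)",
                 nrow(rejected), nrow(d), rejected$line[1],
                 rejected$reason[1]))
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' @rdname read_summary_stats
#' @param records validated summary-stat data.frame.
#' @export
write_summary_stats <- function(records, path) {
  out <- records
  names(out)[names(out) == "snp"] <- "SNP"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) COMPLEMENT[ea] == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns variant-outcome associations to the exposure effect allele so the
#' (bx, by) pairs of two-sample estimators refer to the same allele. Outcome
#' records whose effect/other alleles are swapped relative to the exposure
#' have `by` negated and `eaf` complemented (flag `allele_swap`); records
#' reported on the opposite strand are complement-matched (flag
#' `strand_flip`; a strand flip that also requires a swap is flagged
#' `allele_swap` since that is the sign-changing event). Palindromic (A/T or
#' C/G) variants with either allele frequency within `palindrome_eaf_window`
#' of 0.5 are retained in the table but flagged `dropped_palindromic` and
#' marked `keep = FALSE`; unambiguous palindromes are aligned by allele
#' frequency. Variants with irreconcilable allele sets are dropped with a
#' reason (attribute `"dropped"`).
#'
#' @param exposure,outcome summary-stat data.frames as returned by
#'   [read_summary_stats()] or [cohort_to_summary_stats()].
#' @param palindrome_eaf_window frequency window around 0.5 inside which
#'   palindromic variants are considered unresolvable (default 0.08).
#' @return data.frame of variant-effect pairs: snp, effect_allele,
#'   other_allele, eaf_exposure, eaf_outcome, bx, se_x, by, se_y, flag, keep.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  shared <- intersect(exposure$snp, outcome$snp)
  if (length(shared) == 0) stop("no shared variant IDs between tables")
  ex <- exposure[match(shared, exposure$snp), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp), , drop = FALSE]

  n <- length(shared)
  flag <- character(n)
  keep <- rep(TRUE, n)
  by <- ou$beta
  eaf_out <- ou$eaf
  drop_reason <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    pal <- is_palindromic(ea_x, oa_x)
    if (pal) {
      # textual match cannot distinguish strand from swap; use frequencies
      same_labels <- (ea_y == ea_x && oa_y == oa_x) ||
        (ea_y == oa_x && oa_y == ea_x)
      if (!same_labels) {
        drop_reason[i] <- "irreconcilable alleles"
        next
      }
      if (abs(eaf_out[i] - 0.5) < palindrome_eaf_window ||
          abs(ex$eaf[i] - 0.5) < palindrome_eaf_window) {
        flag[i] <- "dropped_palindromic"
        keep[i] <- FALSE
        next
      }
      if (ea_y == oa_x) {  # labels swapped: orient to exposure effect allele
        by[i] <- -by[i]; eaf_out[i] <- 1 - eaf_out[i]
      }
      if ((eaf_out[i] - 0.5) * (ex$eaf[i] - 0.5) < 0) {
        # frequency disagreement: reported for the complementary strand
        by[i] <- -by[i]; eaf_out[i] <- 1 - eaf_out[i]
        flag[i] <- "allele_swap"
      } else {
        flag[i] <- if (ea_y == oa_x) "allele_swap" else "unchanged"
      }
    } else if (ea_y == ea_x && oa_y == oa_x) {
      flag[i] <- "unchanged"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      by[i] <- -by[i]; eaf_out[i] <- 1 - eaf_out[i]
      flag[i] <- "allele_swap"
    } else if (COMPLEMENT[ea_y] == ea_x && COMPLEMENT[oa_y] == oa_x) {
      flag[i] <- "strand_flip"
    } else if (COMPLEMENT[ea_y] == oa_x && COMPLEMENT[oa_y] == ea_x) {
      by[i] <- -by[i]; eaf_out[i] <- 1 - eaf_out[i]
      flag[i] <- "allele_swap"
    } else {
      drop_reason[i] <- "irreconcilable alleles"
    }
  }

  dropped <- data.frame(snp = shared[!is.na(drop_reason)],
                        reason = drop_reason[!is.na(drop_reason)],
                        stringsAsFactors = FALSE)
  ok <- is.na(drop_reason)
  pairs <- data.frame(
    snp = shared[ok],
    effect_allele = ex$effect_allele[ok],
    other_allele = ex$other_allele[ok],
    eaf_exposure = ex$eaf[ok],
    eaf_outcome = eaf_out[ok],
    bx = ex$beta[ok], se_x = ex$se[ok],
    by = by[ok], se_y = ou$se[ok],
    flag = flag[ok], keep = keep[ok],
    stringsAsFactors = FALSE
  )
  if (!any(pairs$keep)) stop("zero variants survived harmonization")
  attr(pairs, "dropped") <- dropped
  pairs
}
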