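#' Hydroxyl-radical scavenging ability (HRSA) scores
#'
#' A protein's HRSA is an additive, composition-only score built from
#' per-residue scavenging rates measured for free amino acids by EPR of a
#' Fenton system. The measured rate constants are not reprinted here, so
#' the shipped default table is ORDINAL ONLY: it encodes the published
#' rank order Trp > Phe,Leu > Ile > His > Arg > Val > Lys,Tyr,Pro >
#' Gln,Thr,Ser > Glu,Ala,Gly,Asn,Asp as tier values 9..1, and is clearly
#' labelled non-quantitative. Met and Cys are absent from the printed
#' order; the default places these strongly HO.-reactive sulfur residues
#' in the top tier as a documented placeholder, unconstrained by
#' [validate_rank_order()]. Supply a measured table for quantitative work.
#'
#' @name hrsa
NULL

# tiers of the printed rank order, strongest first
.hrsa_tiers <- list(
  c("W"), c("F", "L"), c("I"), c("H"), c("R"), c("V"),
  c("K", "Y", "P"), c("Q", "T", "S"), c("E", "A", "G", "N", "D"))

#' Default ordinal HRSA rate table
#'
#' @return named numeric vector over the 20 residues with attributes
#'   `table_name` ("ordinal-tiers-v1") and `quantitative` (FALSE)
#' @export
default_hrsa_table <- function() {
  rates <- numeric(0)
  vals <- rev(seq_along(.hrsa_tiers))  # 9 .. 1
  for (i in seq_along(.hrsa_tiers))
    rates[.hrsa_tiers[[i]]] <- vals[i]
  rates[c("M", "C")] <- max(vals)  # placeholder: sulfur residues, see above
  rates <- rates[aa_alphabet()]
  structure(rates, table_name = "ordinal-tiers-v1", quantitative = FALSE)
}

#' Validate a rate table against the published rank order
#'
#' TRUE iff every strict inequality between consecutive tiers holds for
#' every residue pair across the tier boundary; ties within a tier are
#' permitted. Residues outside the printed order (Met, Cys) are not
#' constrained.
#'
#' @param table named numeric vector of per-residue rates
#' @return list with `valid` (logical) and `violations` (data frame of
#'   offending higher/lower residue pairs)
#' @export
validate_rank_order <- function(table) {
  miss <- setdiff(aa_alphabet(), names(table))
  if (length(miss) > 0)
    stop("rate table missing residues: ", paste(miss, collapse = ", "))
  if (any(table < 0)) stop("rates must be non-negative")
  viol <- list()
  for (i in seq_len(length(.hrsa_tiers) - 1)) {
    for (hi in .hrsa_tiers[[i]]) {
      for (lo in unlist(.hrsa_tiers[(i + 1):length(.hrsa_tiers)])) {
        if (!(table[[hi]] > table[[lo]]))
          viol[[length(viol) + 1]] <- data.frame(
            higher = hi, lower = lo, stringsAsFactors = FALSE)
      }
    }
  }
  violations <- if (length(viol) > 0) do.call(rbind, viol) else
    data.frame(higher = character(), lower = character(),
               stringsAsFactors = FALSE)
  list(valid = nrow(violations) == 0, violations = violations)
}

#' Score a protein's HRSA
#'
#' Sum (default) or mean of per-residue rates; permutation-invariant by
#' construction. The additive sum grows with protein length, consistent
#' with the published dataset-level range over 100-444 aa proteins.
#'
#' @param sequence residue string
#' @param table named per-residue rate vector, validated against the rank
#'   order before use
#' @param mode `"sum"` or `"mean"`
#' @param validate check the table against the rank order first; disable
#'   only for deliberately synthetic tables (e.g. unit rates)
#' @return list: score, length, mode, table_name
#' @export
score_hrsa <- function(sequence, table = default_hrsa_table(),
                       mode = c("sum", "mean"), validate = TRUE) {
  mode <- match.arg(mode)
  if (validate) {
    v <- validate_rank_order(table)
    if (!v$valid)
      stop("rate table violates the published rank order (",
           nrow(v$violations), " pair(s))")
  }
  r <- .residues(sequence)
  r <- r[r != "X"]
  if (length(r) == 0) stop("sequence has no scoreable residues")
  miss <- setdiff(unique(r), names(table))
  if (length(miss) > 0)
    stop("residue(s) missing from rate table: ", paste(miss, collapse = ", "))
  s <- if (mode == "sum") sum(table[r]) else mean(table[r])
  list(score = s, length = length(r), mode = mode,
       table_name = attr(table, "table_name"))
}

#' HRSA table for a proteome set
#'
#' @param set a `proteome_set`
#' @inheritParams score_hrsa
#' @return data frame: id, length, hrsa, mode, table_name
#' @export
hrsa_table <- function(set, table = default_hrsa_table(),
                       mode = c("sum", "mean")) {
  stopifnot(inherits(set, "proteome_set"))
  mode <- match.arg(mode)
  v <- validate_rank_order(table)
  if (!v$valid) stop("rate table violates the published rank order")
  rows <- lapply(seq_len(nrow(set)), function(i) {
    r <- .residues(set$sequence[i]); r <- r[r != "X"]
    data.frame(id = set$id[i], length = length(r),
               hrsa = if (mode == "sum") sum(table[r]) else mean(table[r]),
               mode = mode,
               table_name = as.character(attr(table, "table_name")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
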