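#' Per-protein physicochemical profiling
#'
#' GRAVY, sliding hydropathy profiles, molecular weight, isoelectric point,
#' residue composition and category percentages, net formal charge, and the
#' hydrophilin criterion (high Gly, strongly negative GRAVY). Conventions
#' follow ExPASy ProtParam: average residue masses plus one water, and the
#' Bjellqvist pK set for the charge curve. X residues are excluded from all
#' scored quantities and from composition denominators.
#'
#' @name physchem
NULL

#' Grand average of hydropathicity (GRAVY)
#'
#' Arithmetic mean of per-residue hydropathies; negative values indicate a
#' hydrophilic protein. The default Kyte--Doolittle scale reproduces the
#' consensus-motif reference values to three decimals.
#'
#' @param sequence residue string
#' @param scale named hydropathy vector, see [hydropathy_scale()]
#' @return dimensionless mean hydropathy
#' @export
gravy <- function(sequence, scale = hydropathy_scale("kd")) {
  r <- .residues(sequence)
  r <- r[r != "X"]
  if (length(r) == 0) stop("sequence has no scoreable residues")
  miss <- setdiff(unique(r), names(scale))
  if (length(miss) > 0)
    stop("residue(s) absent from scale: ", paste(miss, collapse = ", "))
  mean(scale[r])
}

#' Sliding-window mean hydropathy profile
#'
#' @param sequence residue string
#' @param window odd window width in residues (<= sequence length)
#' @param scale named hydropathy vector
#' @return data frame with 1-based window-centre `position` and mean `value`
#' @export
hydropathy_profile <- function(sequence, window = 9,
                               scale = hydropathy_scale("kd")) {
  r <- .residues(sequence, allow_x = FALSE)
  n <- length(r)
  if (window > n) stop("window (", window, ") exceeds sequence length (", n, ")")
  if (window %% 2 == 0) stop("window must be odd")
  h <- as.numeric(scale[r])
  if (anyNA(h)) stop("residue absent from scale")
  cs <- cumsum(c(0, h))
  starts <- seq_len(n - window + 1)
  data.frame(position = starts + (window - 1) %/% 2,
             value = (cs[starts + window] - cs[starts]) / window)
}

#' Molecular weight in kDa
#'
#' Sum of average residue masses plus one water (18.0153 Da), the
#' ProtParam convention, reported in kDa. X residues are skipped.
#'
#' @param sequence residue string
#' @return molecular weight in kDa
#' @export
molecular_weight <- function(sequence) {
  r <- .residues(sequence)
  r <- r[r != "X"]
  if (length(r) == 0) stop("sequence has no scoreable residues")
  (sum(.aa_residue_mass[r]) + .water_mass) / 1000
}

# Net charge of a sequence at a given pH under Henderson-Hasselbalch with
# the Bjellqvist pK set: N-terminus + K,R,H positive; C-terminus + D,E,C,Y
# negative. Vectorised over pH.
.charge_at_ph <- function(counts, nterm_res, ph) {
  pos_pk <- c(.pk_nterm_default, .pk_side[c("K", "R", "H")])
  if (nterm_res %in% names(.pk_nterm)) pos_pk[1] <- .pk_nterm[[nterm_res]]
  pos_n <- c(1, counts["K"], counts["R"], counts["H"])
  neg_pk <- c(.pk_cterm, .pk_side[c("D", "E", "C", "Y")])
  neg_n <- c(1, counts["D"], counts["E"], counts["C"], counts["Y"])
  vapply(ph, function(p) {
    sum(pos_n / (1 + 10^(p - pos_pk))) - sum(neg_n / (1 + 10^(neg_pk - p)))
  }, numeric(1))
}

#' Isoelectric point
#'
#' pH at which the Henderson--Hasselbalch net charge (termini plus the
#' D, E, C, Y, H, K, R side chains, Bjellqvist pK values) crosses zero,
#' found by bisection on [0, 14]. The charge curve is monotone decreasing
#' in pH, so the root is unique.
#'
#' @param sequence residue string
#' @param tol bisection tolerance in pH units
#' @return pI in pH units
#' @export
isoelectric_point <- function(sequence, tol = 0.001) {
  r <- .residues(sequence)
  r <- r[r != "X"]
  if (length(r) == 0) stop("sequence has no scoreable residues")
  counts <- vapply(aa_alphabet(), function(a) sum(r == a), numeric(1))
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.charge_at_ph(counts, r[1], mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Residue composition and category percentages
#'
#' Composition fractions are taken over the scoreable (non-X) length;
#' each category percent is 100 x (members of the set) / length.
#'
#' @param sequence residue string
#' @param scheme a [category_scheme()]
#' @return list with `composition` (named fractions over the 20 residues),
#'   `category_pct` (named percents), and `cys_pct`
#' @export
composition_and_categories <- function(sequence, scheme = category_scheme()) {
  r <- .residues(sequence)
  r <- r[r != "X"]
  if (length(r) == 0) stop("sequence has no scoreable residues")
  n <- length(r)
  comp <- vapply(aa_alphabet(), function(a) sum(r == a) / n, numeric(1))
  cat_pct <- vapply(scheme, function(set) 100 * sum(r %in% set) / n, numeric(1))
  list(composition = comp, category_pct = cat_pct,
       cys_pct = 100 * comp[["C"]])
}

#' Net formal charge from residue counts
#'
#' (#K + #R) - (#D + #E); histidine is excluded by default, matching the
#' worked helix example (4 Lys + 1 Arg - 1 Glu - 1 Asp = +3).
#'
#' @param sequence residue string
#' @param include_his count His as +1
#' @return integer net charge
#' @export
net_formal_charge <- function(sequence, include_his = FALSE) {
  r <- .residues(sequence)
  z <- sum(r %in% c("K", "R")) - sum(r %in% c("D", "E"))
  if (include_his) z <- z + sum(r == "H")
  as.integer(z)
}

#' Hydrophilin criterion
#'
#' TRUE iff Gly percent strictly exceeds `gly_min` and GRAVY is strictly
#' below `gravy_max`. The default GRAVY bound is -1.0: with the printed
#' "< 1" bound nearly every LEA protein qualifies, contradicting the
#' observation that only dehydrin-type proteins are hydrophilins; pass
#' `gravy_max = 1` to reproduce the printed text.
#'
#' @param gly_pct glycine percentage of the sequence
#' @param gravy GRAVY index of the sequence
#' @param gly_min strict lower bound on Gly percent (default 6)
#' @param gravy_max strict upper bound on GRAVY (default -1.0)
#' @return logical
#' @export
is_hydrophilin <- function(gly_pct, gravy, gly_min = 6, gravy_max = -1.0) {
  gly_pct > gly_min & gravy < gravy_max
}

#' Full physicochemical profile of one sequence
#'
#' @param sequence residue string
#' @param scheme a [category_scheme()]
#' @param scale hydropathy scale for GRAVY
#' @param gly_min,gravy_max hydrophilin thresholds, see [is_hydrophilin()]
#' @return list with length, mw (kDa), pi, gravy, composition, category
#'   percents, cys percent, gly percent and the hydrophilin flag
#' @export
physchem_profile <- function(sequence, scheme = category_scheme(),
                             scale = hydropathy_scale("kd"),
                             gly_min = 6, gravy_max = -1.0) {
  cc <- composition_and_categories(sequence, scheme)
  g <- gravy(sequence, scale)
  gly_pct <- 100 * cc$composition[["G"]]
  list(length = sum(strsplit(sequence, "")[[1]] != "X"),
       mw = molecular_weight(sequence),
       pi = isoelectric_point(sequence),
       gravy = g,
       composition = cc$composition,
       category_pct = cc$category_pct,
       cys_pct = cc$cys_pct,
       gly_pct = gly_pct,
       is_hydrophilin = is_hydrophilin(gly_pct, g, gly_min, gravy_max))
}

#' Physicochemical profile table for a proteome set
#'
#' One row per protein with the columns of the standard report:
#' id, length_aa, mw_kda, pi, gravy, pct_charged, pct_polar, pct_nonpolar,
#' pct_aromatic, pct_cys, pct_gly, hydrophilin.
#'
#' @inheritParams physchem_profile
#' @param set a `proteome_set`
#' @return data frame, one row per record
#' @export
physchem_table <- function(set, scheme = category_scheme(),
                           scale = hydropathy_scale("kd"),
                           gly_min = 6, gravy_max = -1.0) {
  stopifnot(inherits(set, "proteome_set"))
  rows <- lapply(seq_len(nrow(set)), function(i) {
    p <- physchem_profile(set$sequence[i], scheme, scale, gly_min, gravy_max)
    data.frame(id = set$id[i], length_aa = p$length, mw_kda = p$mw,
               pi = p$pi, gravy = p$gravy,
               pct_charged = p$category_pct[["charged"]],
               pct_polar = p$category_pct[["polar"]],
               pct_nonpolar = p$category_pct[["nonpolar"]],
               pct_aromatic = p$category_pct[["aromatic"]],
               pct_cys = p$cys_pct, pct_gly = p$gly_pct,
               hydrophilin = p$is_hydrophilin,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = character(), length_aa = integer(),
                      mw_kda = numeric(), pi = numeric(), gravy = numeric(),
                      pct_charged = numeric(), pct_polar = numeric(),
                      pct_nonpolar = numeric(), pct_aromatic = numeric(),
                      pct_cys = numeric(), pct_gly = numeric(),
                      hydrophilin = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Residue-percentage versus GRAVY scatter tables
#'
#' One table per panel of the composition/GRAVY scatter report: for each
#' protein, the percentage of a selected residue set against its GRAVY
#' index, with the hydrophilin flag on the Gly panel. Panels: Gly, Lys+Glu,
#' Ala, Ile+Leu+Val, Cys, Trp, His, Pro.
#'
#' @inheritParams physchem_table
#' @return named list of data frames (id, pct, gravy, and for the Gly
#'   panel a hydrophilin column)
#' @export
gly_gravy_table <- function(set, scheme = category_scheme(),
                            scale = hydropathy_scale("kd"),
                            gly_min = 6, gravy_max = -1.0) {
  stopifnot(inherits(set, "proteome_set"))
  panels <- list(gly = "G", lys_glu = c("K", "E"), ala = "A",
                 ile_leu_val = c("I", "L", "V"), cys = "C", trp = "W",
                 his = "H", pro = "P")
  n <- nrow(set)
  if (n == 0) {
    empty <- data.frame(id = character(), pct = numeric(), gravy = numeric(),
                        stringsAsFactors = FALSE)
    out <- lapply(panels, function(p) empty)
    out$gly$hydrophilin <- logical()
    return(out)
  }
  g <- vapply(set$sequence, gravy, numeric(1), scale = scale,
              USE.NAMES = FALSE)
  res <- lapply(set$sequence, function(s) {
    r <- .residues(s); r[r != "X"]
  })
  out <- lapply(panels, function(members) {
    pct <- vapply(res, function(r) 100 * sum(r %in% members) / length(r),
                  numeric(1))
    data.frame(id = set$id, pct = pct, gravy = g, stringsAsFactors = FALSE)
  })
  out$gly$hydrophilin <- is_hydrophilin(out$gly$pct, g, gly_min, gravy_max)
  out
}
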