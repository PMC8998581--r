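#' Synthetic LEA-like proteomes and DEG tables
#'
#' Generates proteomes with the statistical structure the analysis
#' assumes, so every stage can be exercised without external data. Each
#' family profile states a target length distribution (published per-family
#' mean, spread recovered from the printed standard errors and group
#' sizes), a target GRAVY, and the consensus motifs to embed. Background
#' residues are drawn i.i.d. from a family-specific composition built by
#' exponentially tilting a base composition until the whole protein's
#' expected GRAVY (motifs included, at the expected truncated-normal
#' length) matches the family target. The background model is
#' composition-only on purpose: every downstream statistic is composition-
#' or motif-based, so positional structure beyond the embedded motifs
#' would be untestable decoration.
#'
#' @name synthetic_data
NULL

# published per-family protein counts
.family_counts_default <- c(LEA1 = 24, LEA2 = 127, LEA3 = 18, LEA4 = 96,
                            LEA5 = 11, DEH = 25, SMP = 17)

#' Default family generator profiles
#'
#' One row per family: target mean length and SD (SE x sqrt(n) from the
#' published summary table), target GRAVY, Pfam accession, and the motifs
#' embedded in every generated member (architectures chosen so the truth
#' subgroup is well-defined: LEA1.1, LEA2.2, LEA3.1, LEA4.2, LEA5, DEH1,
#' SMP3).
#'
#' @return data frame with columns family, length_mean, length_sd,
#'   gravy_target, pfam_id, motifs (comma-joined)
#' @export
default_family_profiles <- function() {
  data.frame(
    family = c("LEA1", "LEA2", "LEA3", "LEA4", "LEA5", "DEH", "SMP"),
    length_mean = c(139, 226, 126, 187, 118, 143, 157),
    length_sd = c(5 * sqrt(24), 5 * sqrt(127), 5 * sqrt(18), 7 * sqrt(96),
                  7 * sqrt(11), 9 * sqrt(25), 15 * sqrt(17)),
    gravy_target = c(-0.93, -0.09, -0.59, -1.01, -1.02, -1.40, -0.27),
    pfam_id = c("PF03760", "PF03168", "PF03242", "PF02987", "PF00477",
                "PF00257", "PF04927"),
    motifs = c("M1.1,M1.2", "M2.1,M2.2,M2.6", "M3.1,M3.2", "M4.1,M4.2",
               "M5.1,M5.2", "M6.1,M6.2,M6.3", "M7.1,M7.2"),
    stringsAsFactors = FALSE)
}

# mean of a normal truncated below at `lo`
.tnorm_mean <- function(mu, sd, lo) {
  a <- (lo - mu) / sd
  mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# Family background composition: base = 2:1 blend of the family's embedded
# motif composition and the all-motif average, exponentially tilted so the
# expected whole-protein GRAVY at the expected length hits the target.
.background_composition <- function(profile, registry = load_registry()) {
  kd <- hydropathy_scale("kd")
  motif_names <- strsplit(profile$motifs, ",", fixed = TRUE)[[1]]
  cons <- registry$consensus[match(motif_names, registry$name)]
  comp_of <- function(strs) {
    r <- unlist(strsplit(paste(strs, collapse = ""), "", fixed = TRUE))
    vapply(aa_alphabet(), function(a) sum(r == a), numeric(1)) / length(r)
  }
  base <- (2 * comp_of(cons) + comp_of(registry$consensus)) / 3
  base <- base + 1e-4  # keep support on all 20 residues
  base <- base / sum(base)
  motif_len <- sum(nchar(cons))
  exp_len <- .tnorm_mean(profile$length_mean, profile$length_sd,
                         max(100, motif_len + 5))
  motif_gravy_sum <- sum(nchar(cons) *
                           vapply(cons, gravy, numeric(1), USE.NAMES = FALSE))
  g_bg <- (profile$gravy_target * exp_len - motif_gravy_sum) /
    (exp_len - motif_len)
  tilted_gravy <- function(theta) {
    p <- base * exp(theta * kd)
    sum(p * kd) / sum(p)
  }
  theta <- stats::uniroot(function(t) tilted_gravy(t) - g_bg,
                          lower = -3, upper = 3, tol = 1e-10)$root
  p <- base * exp(theta * kd)
  p / sum(p)
}

#' Generate one synthetic protein
#'
#' Length is drawn from a truncated normal (minimum `min_length`, and
#' always enough room for the motifs); background residues are i.i.d.
#' from the profile's background composition; each motif consensus is
#' embedded verbatim at a random non-overlapping position. Uses the
#' current RNG state: seed with [set.seed()] (or via
#' [generate_proteome()]) for reproducibility.
#'
#' @param profile one row of [default_family_profiles()]
#' @param id record identifier
#' @param registry motif registry
#' @param min_length minimum length (default 100; lower it to exercise the
#'   length filter)
#' @param composition optional precomputed background composition
#' @return single-row `proteome_set` whose description records the family
#'   and the embedded motif positions
#' @export
generate_protein <- function(profile, id = "syn_1",
                             registry = load_registry(), min_length = 100,
                             composition = NULL) {
  motif_names <- strsplit(profile$motifs, ",", fixed = TRUE)[[1]]
  cons <- registry$consensus[match(motif_names, registry$name)]
  if (anyNA(cons))
    stop("unknown motif(s) in profile: ",
         paste(motif_names[is.na(cons)], collapse = ", "))
  motif_total <- sum(nchar(cons))
  lo <- max(min_length, motif_total + 5)
  if (is.null(composition))
    composition <- .background_composition(profile, registry)
  len <- NA
  for (try in 1:1000) {
    cand <- round(stats::rnorm(1, profile$length_mean, profile$length_sd))
    if (cand >= lo) { len <- cand; break }
  }
  if (is.na(len))
    stop("could not draw a length >= ", lo, " for family ", profile$family)
  r <- sample(aa_alphabet(), len, replace = TRUE, prob = composition)
  # joint placement: shuffle motif order, then split the background slack
  # uniformly over the gaps before/between/after the motifs, so a valid
  # non-overlapping arrangement always exists
  k <- length(cons)
  ord <- if (k == 1) 1L else sample(k)
  widths <- nchar(cons)[ord]
  slack <- len - sum(widths)
  cuts <- if (k == 0) integer(0) else
    sort(sample(0:slack, k, replace = TRUE))
  gaps <- diff(c(0, cuts, slack))  # k + 1 non-negative gaps summing to slack
  notes <- character(0)
  pos <- 1L
  for (j in seq_len(k)) {
    pos <- pos + gaps[j]
    w <- widths[j]
    r[pos:(pos + w - 1)] <- strsplit(cons[ord[j]], "", fixed = TRUE)[[1]]
    notes <- c(notes, paste0(motif_names[ord[j]], "@", pos, "-", pos + w - 1))
    pos <- pos + w
  }
  proteome_set(
    id = id, sequence = paste(r, collapse = ""),
    description = paste0("family=", profile$family, " motifs=",
                         paste(notes, collapse = ";")),
    source = "synthetic", provenance = "generate_protein")
}

#' Generate a synthetic proteome with annotations and truth table
#'
#' Honours the per-family counts (defaults: the published family sizes,
#' totalling 318), annotates every record with its family's Pfam
#' accession at e-value 1e-10, and records the true family and subgroup
#' for recovery tests. Fully deterministic given `seed`.
#'
#' @param counts named integer vector family -> count
#' @param seed integer seed for the one global RNG
#' @param profiles data frame as [default_family_profiles()]
#' @param registry motif registry
#' @param min_length minimum protein length
#' @return list: `set` (a `proteome_set`), `annotations` (protein_id,
#'   pfam_id, evalue), `truth` (id, family, subgroup)
#' @export
generate_proteome <- function(counts = .family_counts_default, seed = 1,
                              profiles = default_family_profiles(),
                              registry = load_registry(),
                              min_length = 100) {
  stopifnot(all(counts >= 0), all(names(counts) %in% profiles$family))
  set.seed(seed)
  sets <- list(); ann <- list(); truth <- list()
  for (fam in names(counts)) {
    n <- counts[[fam]]
    if (n == 0) next
    prof <- profiles[profiles$family == fam, ]
    comp <- .background_composition(prof, registry)
    motif_names <- strsplit(prof$motifs, ",", fixed = TRUE)[[1]]
    subgroup <- assign_subgroup(fam, motif_names)
    for (i in seq_len(n)) {
      id <- sprintf("syn_%s_%03d", fam, i)
      rec <- generate_protein(prof, id, registry, min_length, comp)
      sets[[length(sets) + 1]] <- rec
      ann[[length(ann) + 1]] <- data.frame(
        protein_id = id, pfam_id = prof$pfam_id, evalue = 1e-10,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1]] <- data.frame(
        id = id, family = fam, subgroup = subgroup,
        stringsAsFactors = FALSE)
    }
  }
  if (length(sets) == 0) {
    empty_set <- proteome_set(id = "x", sequence = "A")[0, ]
    class(empty_set) <- c("proteome_set", "data.frame")
    return(list(set = empty_set,
                annotations = data.frame(protein_id = character(),
                                         pfam_id = character(),
                                         evalue = numeric(),
                                         stringsAsFactors = FALSE),
                truth = data.frame(id = character(), family = character(),
                                   subgroup = character(),
                                   stringsAsFactors = FALSE)))
  }
  all_set <- do.call(rbind, sets)
  attr(all_set, "provenance") <- paste0("generate_proteome:seed=", seed)
  class(all_set) <- c("proteome_set", "data.frame")
  list(set = all_set, annotations = do.call(rbind, ann),
       truth = do.call(rbind, truth))
}

#' Generate a synthetic DEG table over a truth table
#'
#' Assigns log2 fold changes from a three-part mixture: the up fraction
#' draws |N(5, 2)| + 2, the down fraction -(|N(2, 1)| + 2), the remainder
#' null N(0, 0.5). FDR values are small (uniform on [0, 0.01]) for
#' non-null genes and uniform on [0, 1] for null genes. Fractions are
#' applied by count rounding, so e.g. 0.76/0.24 on 88 genes yields exactly
#' 67 up and 21 down.
#'
#' @param truth truth table from [generate_proteome()] (columns id,
#'   subgroup), one gene per protein
#' @param frac_up,frac_down mixture fractions (must lie in [0, 1] and sum
#'   to at most 1; the remainder is null)
#' @param seed integer seed
#' @return data frame: rs_id, leap_id, subgroup, log2fc, fdr, class
#'   (up/down/null)
#' @export
generate_deg_table <- function(truth, frac_up = 0.76, frac_down = 0.24,
                               seed = 1) {
  if (frac_up < 0 || frac_down < 0 || frac_up > 1 || frac_down > 1 ||
      frac_up + frac_down > 1)
    stop("fractions must lie in [0, 1] and sum to at most 1")
  set.seed(seed)
  n <- nrow(truth)
  n_up <- round(frac_up * n)
  n_down <- round(frac_down * n)
  if (n_up + n_down > n) n_down <- n - n_up
  cls <- sample(rep(c("up", "down", "null"),
                    c(n_up, n_down, n - n_up - n_down)))
  log2fc <- numeric(n); fdr <- numeric(n)
  for (i in seq_len(n)) {
    if (cls[i] == "up") {
      log2fc[i] <- abs(stats::rnorm(1, 5, 2)) + 2
      fdr[i] <- stats::runif(1, 0, 0.01)
    } else if (cls[i] == "down") {
      log2fc[i] <- -(abs(stats::rnorm(1, 2, 1)) + 2)
      fdr[i] <- stats::runif(1, 0, 0.01)
    } else {
      log2fc[i] <- stats::rnorm(1, 0, 0.5)
      fdr[i] <- stats::runif(1)
    }
  }
  data.frame(rs_id = paste0("Rs_", seq_len(n)), leap_id = truth$id,
             subgroup = truth$subgroup, log2fc = log2fc, fdr = fdr,
             class = cls, stringsAsFactors = FALSE)
}
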