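#' Helical-wheel amphipathicity analysis
#'
#' HeliQuest-style analysis of short windows as ideal alpha-helices:
#' residue i sits at angle (i-1) x delta on the wheel (delta = 100 degrees
#' per residue for the canonical alpha-helix), the hydrophobic moment is
#' the Eisenberg vector sum, and faces are maximal contiguous arcs of
#' hydrophobic / positive / negative residues in wheel order. An "A-type"
#' helix carries all three faces at once. A heuristic hydropathy scan
#' stands in for transmembrane-helix prediction.
#'
#' @name helix
NULL

.hydrophobic_set_default <- c("A", "V", "L", "I", "M", "F", "W", "C")

#' Hydrophobic moment of a window
#'
#' Magnitude of sum_n H_n (cos n delta, sin n delta) divided by the window
#' length (Eisenberg mean moment, the HeliQuest convention). The default
#' scale is Fauchere--Pliska, HeliQuest's.
#'
#' @param window residue string
#' @param scale named hydropathy vector, default [hydropathy_scale]("fp")
#' @param delta angular step per residue in degrees (default 100)
#' @return moment magnitude in scale units
#' @export
hydrophobic_moment <- function(window, scale = hydropathy_scale("fp"),
                               delta = 100) {
  r <- .residues(window, allow_x = FALSE)
  miss <- setdiff(unique(r), names(scale))
  if (length(miss) > 0)
    stop("residue(s) absent from scale: ", paste(miss, collapse = ", "))
  h <- as.numeric(scale[r])
  ang <- (seq_along(r) - 1) * delta * pi / 180
  sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / length(r)
}

#' Helical wheel with face segmentation
#'
#' Assigns wheel angles, computes the hydrophobic moment, mean
#' hydrophobicity and net formal charge of the window, and reports maximal
#' contiguous arcs (in wheel order) of hydrophobic residues, of {K,R} and
#' of {D,E} as faces. The A-type flag requires a hydrophobic AND a
#' positive AND a negative face.
#'
#' @param window residue string, 6 to 54 residues
#' @param scale named hydropathy vector for the moment and mean
#' @param delta angular step per residue in degrees
#' @param hydrophobic_set residues counted as hydrophobic for face calls
#' @return list with `wheel` (data frame: index, residue, angle_deg),
#'   `mu_h`, `mean_h`, `z`, `faces` (data frame: kind, member_indices,
#'   arc_span_deg), and `a_type`
#' @export
wheel_and_faces <- function(window, scale = hydropathy_scale("fp"),
                            delta = 100,
                            hydrophobic_set = .hydrophobic_set_default) {
  r <- .residues(window, allow_x = FALSE)
  n <- length(r)
  if (n < 6 || n > 54)
    stop("window length ", n, " outside [6, 54]")
  ang <- ((seq_len(n) - 1) * delta) %% 360
  wheel <- data.frame(index = seq_len(n), residue = r, angle_deg = ang,
                      stringsAsFactors = FALSE)
  member_sets <- list(hydrophobic = r %in% hydrophobic_set,
                      positive = r %in% c("K", "R"),
                      negative = r %in% c("D", "E"))
  ord <- order(ang, seq_len(n))  # wheel order, ties by sequence index
  faces <- list()
  for (kind in names(member_sets)) {
    memb_in_order <- member_sets[[kind]][ord]
    if (!any(memb_in_order)) next
    if (all(memb_in_order)) {
      faces[[length(faces) + 1]] <- data.frame(
        kind = kind,
        member_indices = paste(ord, collapse = ","),
        arc_span_deg = 360, stringsAsFactors = FALSE)
      next
    }
    # circular runs of TRUE in wheel order
    runs <- rle(memb_in_order)
    bounds <- cumsum(runs$lengths)
    starts <- c(1, utils::head(bounds, -1) + 1)
    segs <- Map(function(s, e, v) if (v) s:e else NULL,
                starts, bounds, runs$values)
    segs <- Filter(Negate(is.null), segs)
    # merge wrap-around: last run TRUE and first run TRUE
    if (length(segs) > 1 && runs$values[1] && runs$values[length(runs$values)]) {
      segs[[1]] <- c(segs[[length(segs)]], segs[[1]])
      segs[[length(segs)]] <- NULL
    }
    for (seg in segs) {
      idx <- ord[seg]
      # arc span: circular distance from first to last member along the arc
      span <- if (length(idx) == 1) 0 else sum(diff(ang[idx]) %% 360)
      faces[[length(faces) + 1]] <- data.frame(
        kind = kind, member_indices = paste(idx, collapse = ","),
        arc_span_deg = span, stringsAsFactors = FALSE)
    }
  }
  faces <- if (length(faces) > 0) do.call(rbind, faces) else
    data.frame(kind = character(), member_indices = character(),
               arc_span_deg = numeric(), stringsAsFactors = FALSE)
  rownames(faces) <- NULL
  a_type <- all(c("hydrophobic", "positive", "negative") %in% faces$kind)
  list(wheel = wheel,
       mu_h = hydrophobic_moment(window, scale, delta),
       mean_h = mean(as.numeric(scale[r])),
       z = net_formal_charge(window),
       faces = faces, a_type = a_type)
}

#' Best amphipathic window of a sequence
#'
#' Slides a window of `width` residues and returns the analysis of the
#' window maximising the hydrophobic moment; ties go to the smallest
#' start.
#'
#' @param sequence residue string
#' @param width window width in residues (default 11)
#' @inheritParams wheel_and_faces
#' @return the [wheel_and_faces()] result for the winning window, plus
#'   `start_1based` and `end_1based`
#' @export
scan_best_window <- function(sequence, width = 11,
                             scale = hydropathy_scale("fp"), delta = 100,
                             hydrophobic_set = .hydrophobic_set_default) {
  r <- .residues(sequence, allow_x = FALSE)
  n <- length(r)
  if (n < width) stop("sequence length ", n, " shorter than width ", width)
  h <- as.numeric(scale[r])
  ang <- (seq_along(r) - 1) * delta * pi / 180
  # mu at window starting s uses local angles (i - s)*delta; rotating all
  # angles by a constant leaves the magnitude unchanged, so global angles
  # can be used directly.
  cx <- cumsum(c(0, h * cos(ang)))
  sx <- cumsum(c(0, h * sin(ang)))
  starts <- seq_len(n - width + 1)
  mu <- sqrt((cx[starts + width] - cx[starts])^2 +
             (sx[starts + width] - sx[starts])^2) / width
  best <- which.max(mu)  # first maximum = smallest start
  win <- substr(paste(r, collapse = ""), best, best + width - 1)
  out <- wheel_and_faces(win, scale, delta, hydrophobic_set)
  out$start_1based <- as.integer(best)
  out$end_1based <- as.integer(best + width - 1)
  out
}

#' Heuristic transmembrane-helix candidate scan
#'
#' Maximal non-overlapping windows of `width` residues whose mean
#' Kyte--Doolittle hydropathy is at least `min_mean_kd`, selected greedily
#' by descending mean (ties by smaller start). A crude stand-in for a real
#' topology predictor: a membrane-spanning helix is ~20 strongly
#' hydrophobic residues.
#'
#' @param sequence residue string
#' @param width window width (default 19)
#' @param min_mean_kd threshold on the window mean (default 1.6)
#' @param scale hydropathy scale (default Kyte--Doolittle)
#' @return data frame: start_1based, end_1based, mean_kd
#' @export
tmh_candidate_scan <- function(sequence, width = 19, min_mean_kd = 1.6,
                               scale = hydropathy_scale("kd")) {
  r <- .residues(sequence, allow_x = FALSE)
  n <- length(r)
  if (width > n) stop("width exceeds sequence length")
  h <- as.numeric(scale[r])
  cs <- cumsum(c(0, h))
  starts <- seq_len(n - width + 1)
  # rounded for stable greedy ordering: windows of identical composition
  # must compare as exact ties regardless of summation order
  means <- round((cs[starts + width] - cs[starts]) / width, 9)
  cand <- which(means >= min_mean_kd)
  sel <- integer(0)
  for (k in cand[order(-means[cand], cand)]) {
    if (all(abs(k - sel) >= width)) sel <- c(sel, k)
  }
  sel <- sort(sel)
  data.frame(start_1based = sel, end_1based = sel + width - 1L,
             mean_kd = means[sel])
}

#' Per-protein best-window helix table
#'
#' One row per protein: the window of `width` residues maximising the
#' hydrophobic moment, with moment, mean hydrophobicity, net charge and
#' the A-type flag. Proteins shorter than `width` are skipped.
#'
#' @param set a `proteome_set`
#' @inheritParams scan_best_window
#' @return data frame: id, start_1based, end_1based, window, mu_h, mean_h,
#'   z, a_type
#' @export
helix_table <- function(set, width = 11, scale = hydropathy_scale("fp"),
                        delta = 100,
                        hydrophobic_set = .hydrophobic_set_default) {
  stopifnot(inherits(set, "proteome_set"))
  rows <- lapply(seq_len(nrow(set)), function(i) {
    if (nchar(set$sequence[i]) < width) return(NULL)
    b <- scan_best_window(set$sequence[i], width, scale, delta,
                          hydrophobic_set)
    data.frame(id = set$id[i], start_1based = b$start_1based,
               end_1based = b$end_1based,
               window = paste(b$wheel$residue, collapse = ""),
               mu_h = b$mu_h, mean_h = b$mean_h, z = b$z,
               a_type = b$a_type, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = character(), start_1based = integer(),
                      end_1based = integer(), window = character(),
                      mu_h = numeric(), mean_h = numeric(), z = integer(),
                      a_type = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
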