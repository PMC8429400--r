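## Lectin-microarray differential fingerprints: replicate aggregation,
## subtracted fingerprints (delta, t-test p, signed fold change),
## cross-pair intersection/concordance, heat-map ordering, radar export.

#' Default 43-lectin panel
#'
#' A fixed, ordered panel of 43 lectin names with glycotope annotations
#' (pass-through strings). The panel order anchors fingerprint
#' alignment; arbitrary panels can be supplied wherever a panel argument
#' is accepted.
#'
#' @return Object of class `lectin_panel`: `names` (character, unique)
#'   and `glycotope` (named character).
#' @export
default_lectin_panel <- function() {
  nm <- c("HPA", "VVA", "DBA", "SBA", "BPL", "PNA", "ACA", "ABA", "Jacalin",
          "MPA", "WGA", "sWGA", "GSL-II", "DSA", "LEL", "STL", "UDA",
          "PHA-L", "PHA-E", "ConA", "sConA", "GNL", "HHL", "NPA", "PSA",
          "LCA", "AAL", "AOL", "UEA-I", "LTL", "RCA120", "ECA", "GSL-I",
          "SSA", "SNA", "TJA-I", "MAL-I", "MAL-II", "WFA", "Calsepa",
          "TxLC-I", "EEL", "PTL-I")
  gly <- c("Tn (GalNAc-O-Ser/Thr)", "Tn", "GalNAc-alpha", "GalNAc",
           "Gal/GalNAc", "T (Gal-b1,3-GalNAc)", "T/Tn", "T", "T/Tn",
           "T/Tn", "GlcNAc/sialic acid", "GlcNAc", "GlcNAc", "LacNAc",
           "LacNAc oligomer", "GlcNAc oligomer", "GlcNAc",
           "b1,6-branched N-glycan", "bisecting GlcNAc", "high mannose",
           "high mannose", "terminal mannose", "mannose", "mannose",
           "core fucose", "core fucose", "fucose", "core fucose",
           "Fuc-a1,2-Gal", "Fuc-a1,3-GlcNAc", "terminal Gal (complex N)",
           "LacNAc", "Gal-alpha", "Sia-a2,6", "Sia-a2,6", "Sia-a2,6",
           "Sia-a2,3", "Sia-a2,3", "LacdiNAc", "mannose (complex)",
           "GalNAc complex", "Gal-a1,3", "Gal-a1,3")
  names(gly) <- nm
  structure(list(names = nm, glycotope = gly), class = "lectin_panel")
}

.as_panel <- function(panel) {
  if (inherits(panel, "lectin_panel")) return(panel$names)
  if (is.character(panel)) {
    if (anyDuplicated(panel)) stop("panel names must be unique")
    return(panel)
  }
  stop("panel must be a lectin_panel or character vector")
}

#' Aggregate spot intensities into per-condition fingerprints
#'
#' Spot intensities are averaged within each replicate (array) per
#' lectin, then summarized across replicates to a condition mean with SD
#' and the replicate count n. The result is invariant to the ordering of
#' spots and to replicate relabeling.
#'
#' @param spots A data.frame with columns `condition`, `replicate_id`,
#'   `lectin`, `spot_index`, `intensity` (>= 0).
#' @param panel Lectin panel (order used for alignment); default the
#'   43-lectin panel restricted to lectins present.
#' @return Named list (one element per condition) of `fingerprint`
#'   objects: data.frames with `lectin`, `mean`, `sd`, `n`.
#' @export
aggregate_spots <- function(spots, panel = NULL) {
  req <- c("condition", "replicate_id", "lectin", "spot_index", "intensity")
  miss <- setdiff(req, names(spots))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(spots$intensity < 0)) stop("intensities must be >= 0")
  lect <- if (is.null(panel)) unique(as.character(spots$lectin))
          else .as_panel(panel)
  out <- list()
  for (cond in unique(as.character(spots$condition))) {
    sc <- spots[spots$condition == cond, ]
    # per-replicate means per lectin
    repmean <- stats::aggregate(intensity ~ lectin + replicate_id,
                                data = sc, FUN = mean)
    gaps <- setdiff(lect, unique(as.character(repmean$lectin)))
    if (length(gaps))
      stop("condition '", cond, "': no spots for lectin(s): ",
           paste(gaps, collapse = ", "))
    m <- sd_ <- n <- numeric(length(lect))
    reps <- list()
    for (i in seq_along(lect)) {
      v <- repmean$intensity[repmean$lectin == lect[i]]
      nrep <- length(v)
      if (nrep < 2L)
        stop("condition '", cond, "', lectin '", lect[i],
             "': need >= 2 replicates, found ", nrep)
      m[i] <- mean(v); sd_[i] <- stats::sd(v); n[i] <- nrep
      reps[[lect[i]]] <- v
    }
    fp <- data.frame(lectin = lect, mean = m, sd = sd_, n = n,
                     stringsAsFactors = FALSE)
    attr(fp, "replicate_means") <- reps
    class(fp) <- c("fingerprint", "data.frame")
    out[[cond]] <- fp
  }
  out
}

#' Subtracted fingerprint between two conditions
#'
#' Per lectin: `delta = mean_A - mean_B`; a two-tailed Student's t test
#' (pooled variance by default) on the replicate means; and a signed
#' fold change `mean_A / mean_B` when A >= B, else `-mean_B / mean_A`
#' (so a twofold decrease is reported as -2). No multiple-testing
#' correction is applied by default, matching raw p < 0.05 selection
#' over the panel; Benjamini-Hochberg is available via `adjust = "BH"`.
#'
#' @param fp_a,fp_b `fingerprint` objects from [aggregate_spots()]
#'   (aligned panels, replicate means attached).
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pooled-variance Student test (default) or Welch.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Object of class `subtracted_fingerprint`: data.frame with
#'   `lectin`, `delta`, `p_value`, `significant`, `signed_fold_change`
#'   (NA when the smaller mean is 0), plus attribute `alpha`.
#' @export
subtract_fingerprints <- function(fp_a, fp_b, alpha = 0.05,
                                  var_equal = TRUE,
                                  adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(fp_a, "fingerprint"), inherits(fp_b, "fingerprint"))
  if (!identical(fp_a$lectin, fp_b$lectin))
    stop("fingerprints have mismatched lectin panels")
  ra <- attr(fp_a, "replicate_means")
  rb <- attr(fp_b, "replicate_means")
  nl <- nrow(fp_a)
  delta <- fp_a$mean - fp_b$mean
  p <- numeric(nl)
  fold <- numeric(nl)
  for (i in seq_len(nl)) {
    va <- ra[[fp_a$lectin[i]]]
    vb <- rb[[fp_b$lectin[i]]]
    p[i] <- if (stats::sd(c(va, vb)) == 0) 1 else
      stats::t.test(va, vb, var.equal = var_equal)$p.value
    ma <- fp_a$mean[i]; mb <- fp_b$mean[i]
    fold[i] <- if (min(ma, mb) <= 0) NA_real_
               else if (ma >= mb) ma / mb else -mb / ma
  }
  padj <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  out <- data.frame(lectin = fp_a$lectin, delta = delta, p_value = p,
                    significant = padj < alpha,
                    signed_fold_change = fold, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  class(out) <- c("subtracted_fingerprint", "data.frame")
  out
}

#' Intersect subtracted fingerprints from two cell pairs
#'
#' Finds the lectins significant in both pairs (`common`) and, among
#' those, the ones whose difference has the same sign in both pairs
#' (`concordant`) -- the procedure that nominates glycotopes whose
#' change tracks the phenotype across independent cell pairs.
#'
#' @param sf1,sf2 `subtracted_fingerprint` objects on the same panel.
#' @return Object of class `cross_pair_result`: `common`, `concordant`
#'   (character vectors, panel order) and `folds` (data.frame of per-pair
#'   signed fold changes for the common lectins).
#' @export
intersect_pairs <- function(sf1, sf2) {
  stopifnot(inherits(sf1, "subtracted_fingerprint"),
            inherits(sf2, "subtracted_fingerprint"))
  if (!identical(sf1$lectin, sf2$lectin))
    stop("subtracted fingerprints are on different panels")
  common <- sf1$lectin[sf1$significant & sf2$significant]
  i1 <- match(common, sf1$lectin)
  conc <- common[sign(sf1$delta[i1]) == sign(sf2$delta[match(common,
                                                             sf2$lectin)])]
  folds <- data.frame(lectin = common,
                      fold_pair1 = sf1$signed_fold_change[i1],
                      fold_pair2 = sf2$signed_fold_change[match(common,
                                                                sf2$lectin)],
                      stringsAsFactors = FALSE)
  structure(list(common = common, concordant = conc, folds = folds),
            class = "cross_pair_result")
}

#' Order lectins by a reference condition for heat-map display
#'
#' Sorts lectins from largest to smallest mean intensity in the
#' reference condition and reindexes every condition to that order.
#' Ties are broken by the original panel order (stable sort).
#'
#' @param fingerprints Named list of `fingerprint` objects (aligned
#'   panels).
#' @param reference Name of the reference condition.
#' @return List with `order` (lectin names, descending reference mean)
#'   and `matrix` (lectins x conditions, reordered means).
#' @export
heatmap_order <- function(fingerprints, reference) {
  if (!reference %in% names(fingerprints))
    stop("reference condition '", reference, "' not present")
  ref <- fingerprints[[reference]]
  o <- order(-ref$mean)  # stable: ties keep panel order
  lect <- ref$lectin[o]
  mat <- vapply(fingerprints, function(fp) {
    if (!identical(fp$lectin, ref$lectin))
      stop("fingerprints have mismatched panels")
    fp$mean[o]
  }, numeric(length(o)))
  rownames(mat) <- lect
  list(order = lect, matrix = mat)
}

#' Export a subtracted fingerprint for radar/bar plots
#'
#' Per-lectin delta and signed fold change in panel order with an
#' explicit zero-baseline column (the "red ring" of a radar plot).
#'
#' @param sf A `subtracted_fingerprint`.
#' @return data.frame with `lectin`, `delta`, `signed_fold_change`,
#'   `significant`, `baseline` (all 0).
#' @export
radar_export <- function(sf) {
  stopifnot(inherits(sf, "subtracted_fingerprint"))
  data.frame(lectin = sf$lectin, delta = sf$delta,
             signed_fold_change = sf$signed_fold_change,
             significant = sf$significant,
             baseline = 0, stringsAsFactors = FALSE)
}

#' Read a minimal GenePix GPR dialect
#'
#' Parses the subset of the GenePix results format needed here: an
#' ATF-style header (`"key=value"` lines, possibly quoted) followed by a
#' tab-separated block with named columns; only `Name` (lectin) and the
#' first `F... Median` column are consumed.
#'
#' @param path Path to a `.gpr` file.
#' @param condition,replicate_id Labels attached to the returned rows.
#' @return data.frame in [aggregate_spots()] input format.
#' @export
read_gpr <- function(path, condition = "sample", replicate_id = "r1") {
  lines <- readLines(path, warn = FALSE)
  # locate the column-header line: first line containing a "Name" field
  hdr <- which(vapply(lines, function(l)
    grepl("\t", l) && "Name" %in% gsub('"', "", strsplit(l, "\t")[[1]]),
    logical(1)))[1]
  if (is.na(hdr)) stop("no column header with a Name field found in ", path)
  tab <- utils::read.delim(text = paste(lines[hdr:length(lines)],
                                        collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  names(tab) <- gsub('"', "", names(tab))
  fcol <- grep("^F[0-9]* Median$", names(tab), value = TRUE)[1]
  if (is.na(fcol)) stop("no 'F<wavelength> Median' column in ", path)
  data.frame(condition = condition, replicate_id = replicate_id,
             lectin = as.character(tab$Name),
             spot_index = seq_len(nrow(tab)),
             intensity = as.numeric(tab[[fcol]]),
             stringsAsFactors = FALSE)
}
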