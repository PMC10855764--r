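#' Construct an n-alkane retention ladder
#'
#' An alkane ladder maps carbon numbers of co-injected n-alkane standards
#' (C7--C30) to their retention times and anchors the linear retention index
#' (LRI) scale: the alkane with `n` carbons has LRI `100 * n` by definition.
#'
#' @param carbons Integer vector of carbon numbers, each in 7..30.
#' @param rt_min Numeric vector of retention times in minutes, strictly
#'   increasing with carbon number.
#' @return An object of class `alkane_ladder`: a data frame with columns
#'   `carbon` and `rt_min`, sorted by carbon number.
#' @examples
#' ladder <- alkane_ladder(7:12, c(2, 4, 7, 11, 16, 22))
#' linear_retention_index(11, ladder)  # 1000 at the C10 anchor
#' @export
alkane_ladder <- function(carbons, rt_min) {
  if (length(carbons) != length(rt_min)) {
    stop("`carbons` and `rt_min` must have the same length", call. = FALSE)
  }
  if (length(carbons) < 2) {
    stop("an alkane ladder needs at least two anchors", call. = FALSE)
  }
  carbons <- as.integer(carbons)
  if (anyNA(carbons) || any(carbons < 7L) || any(carbons > 30L)) {
    stop("carbon numbers must lie in 7..30", call. = FALSE)
  }
  if (anyDuplicated(carbons)) {
    stop("duplicated carbon numbers in ladder", call. = FALSE)
  }
  ord <- order(carbons)
  carbons <- carbons[ord]
  rt_min <- as.numeric(rt_min)[ord]
  if (any(!is.finite(rt_min)) || any(rt_min <= 0)) {
    stop("retention times must be finite and positive", call. = FALSE)
  }
  if (any(diff(rt_min) <= 0)) {
    stop("ladder retention times must be strictly increasing in carbon number",
         call. = FALSE)
  }
  structure(data.frame(carbon = carbons, rt_min = rt_min),
            class = c("alkane_ladder", "data.frame"))
}

#' Linear retention index by the van den Dool and Kratz formula
#'
#' Converts a retention time to the dimensionless LRI scale by piecewise-linear
#' interpolation between the bracketing n-alkane anchors:
#' `LRI = 100 * (n + (n' - n) * (rt - t_n) / (t_n' - t_n))`, where `t_n` is the
#' retention time of the last alkane eluting at or before `rt` and `n'` the
#' next anchor. At an anchor the LRI is exactly `100 * n`. No extrapolation is
#' performed outside the ladder span.
#'
#' @param rt Numeric vector of retention times in minutes.
#' @param ladder An [alkane_ladder()].
#' @return Numeric vector of retention indices.
#' @export
linear_retention_index <- function(rt, ladder) {
  stopifnot(inherits(ladder, "alkane_ladder"))
  rt <- as.numeric(rt)
  tn <- ladder$rt_min
  cn <- ladder$carbon
  if (any(rt < tn[1] | rt > tn[length(tn)])) {
    stop("retention time outside the ladder span [",
         tn[1], ", ", tn[length(tn)], "] min; no extrapolation", call. = FALSE)
  }
  # index of the last anchor eluting at or before rt (capped so rt at the top
  # anchor interpolates within the final segment)
  i <- findInterval(rt, tn)
  i <- pmin(i, length(tn) - 1L)
  100 * (cn[i] + (cn[i + 1L] - cn[i]) * (rt - tn[i]) / (tn[i + 1L] - tn[i]))
}

#' Normalize peak areas to the internal standard
#'
#' Divides every analyte area in one sample's peak list by the area of the
#' internal-standard (IS) peak, identified by its quantifier mass-to-charge
#' ratio (default m/z 59, the 3-octanol quantifier). The IS record is removed
#' from the output.
#'
#' @param peaks Data frame of peak records for a single sample with at least
#'   columns `mz` and `area` (see [read_peak_table()] for the full layout).
#' @param is_mz Integer quantifier m/z identifying the internal standard.
#' @return `peaks` without the IS row and with `area` replaced by the
#'   dimensionless IS-normalized area (column `norm_area`).
#' @export
normalize_to_internal_standard <- function(peaks, is_mz = 59L) {
  stopifnot(is.data.frame(peaks), all(c("mz", "area") %in% names(peaks)))
  is_idx <- which(peaks$mz == is_mz)
  if (length(is_idx) == 0L) {
    stop("no internal-standard peak with m/z ", is_mz, " found", call. = FALSE)
  }
  if (length(is_idx) > 1L) {
    stop("ambiguous internal standard: ", length(is_idx),
         " peaks with m/z ", is_mz, call. = FALSE)
  }
  is_area <- peaks$area[is_idx]
  if (!is.finite(is_area) || is_area <= 0) {
    stop("internal-standard area must be positive, got ", is_area, call. = FALSE)
  }
  out <- peaks[-is_idx, , drop = FALSE]
  out$norm_area <- out$area / is_area
  out$area <- NULL
  rownames(out) <- NULL
  out
}

#' Annotate a peak by its experimental retention index
#'
#' Matches an experimental LRI against a table of reference indices and
#' returns the compound with the smallest absolute index difference, provided
#' that difference is within `tolerance`; otherwise `NA` (unassigned). Exact
#' ties are broken by lexicographic compound name, with a warning.
#'
#' @param lri_e Numeric vector of experimental retention indices.
#' @param reference Named numeric vector mapping compound name to reference LRI.
#' @param tolerance Maximum absolute LRI difference accepted for an assignment.
#'   Defaults to 10 index units, a typical inter-laboratory spread.
#' @return Character vector of compound names, `NA` where unassigned.
#' @export
annotate_by_lri <- function(lri_e, reference, tolerance = 10) {
  if (length(reference) == 0L || is.null(names(reference))) {
    stop("`reference` must be a non-empty named numeric vector", call. = FALSE)
  }
  stopifnot(tolerance > 0)
  ref <- reference[order(names(reference))]  # lexicographic tie-break
  vapply(as.numeric(lri_e), function(x) {
    d <- abs(x - ref)
    j <- which(d == min(d))
    if (length(j) > 1L) {
      warning("LRI tie at index ", x, " between ",
              paste(names(ref)[j], collapse = ", "),
              "; lexicographically first taken", call. = FALSE)
      j <- j[1L]
    }
    if (d[j] <= tolerance) names(ref)[j] else NA_character_
  }, character(1))
}

#' Assemble a samples-by-compound feature table
#'
#' Builds the wide analysis matrix from normalized per-sample peak lists: the
#' union of compounds across samples forms the columns, samples missing a
#' compound get an exact 0 (undetected peaks are treated as absent, which is
#' informative for irradiation-only volatiles), and columns are ordered by
#' chemical class then compound name.
#'
#' @param peaks Data frame with columns `sample_id`, `compound`, `norm_area`
#'   covering all samples.
#' @param metadata Data frame with columns `sample_id`, `cheese`, `dose_kgy`;
#'   one row per sample, doses drawn from 0/2/4/6 kGy.
#' @param class_map Optional named character vector mapping compound to its
#'   chemical class, used for column ordering and carried as an attribute.
#' @return A `voc_table`: data frame with columns `sample_id`, `cheese`,
#'   `dose_kgy` followed by one numeric column per compound, plus attributes
#'   `class_map` and (if supplied upstream) `discriminant`.
#' @export
build_feature_table <- function(peaks, metadata, class_map = NULL) {
  stopifnot(is.data.frame(peaks),
            all(c("sample_id", "compound", "norm_area") %in% names(peaks)))
  stopifnot(is.data.frame(metadata),
            all(c("sample_id", "cheese", "dose_kgy") %in% names(metadata)))
  if (nrow(peaks) == 0L || nrow(metadata) == 0L) {
    stop("empty peak or metadata table", call. = FALSE)
  }
  dup <- duplicated(peaks[c("sample_id", "compound")])
  if (any(dup)) {
    bad <- peaks$sample_id[dup][1]
    stop("duplicate (sample, compound) records; first offending sample: ",
         bad, call. = FALSE)
  }
  missing_meta <- setdiff(unique(peaks$sample_id), metadata$sample_id)
  if (length(missing_meta) > 0L) {
    stop("samples without metadata: ",
         paste(utils::head(missing_meta, 3), collapse = ", "), call. = FALSE)
  }
  if (!all(metadata$dose_kgy %in% c(0, 2, 4, 6))) {
    stop("dose labels must be one of 0, 2, 4, 6 kGy", call. = FALSE)
  }

  compounds <- sort(unique(peaks$compound))
  if (!is.null(class_map)) {
    known <- intersect(compounds, names(class_map))
    compounds <- c(known[order(class_map[known], known)], setdiff(compounds, known))
  }
  samples <- metadata$sample_id
  m <- matrix(0, nrow = length(samples), ncol = length(compounds),
              dimnames = list(samples, compounds))
  m[cbind(match(peaks$sample_id, samples), match(peaks$compound, compounds))] <-
    peaks$norm_area

  out <- data.frame(sample_id = samples,
                    cheese = metadata$cheese,
                    dose_kgy = metadata$dose_kgy,
                    m, check.names = FALSE, row.names = NULL)
  new_voc_table(out, class_map = class_map)
}

new_voc_table <- function(df, class_map = NULL, discriminant = NULL) {
  structure(df,
            class_map = class_map,
            discriminant = discriminant,
            class = c("voc_table", "data.frame"))
}

#' Extract the numeric compound matrix from a feature table
#'
#' @param x A `voc_table`.
#' @return Numeric matrix (samples x compounds) with sample ids as row names.
#' @export
voc_matrix <- function(x) {
  stopifnot(inherits(x, "voc_table"))
  meta <- c("sample_id", "cheese", "dose_kgy")
  m <- as.matrix(x[, setdiff(names(x), meta), drop = FALSE])
  rownames(m) <- x$sample_id
  storage.mode(m) <- "double"
  m
}

#' @export
print.voc_table <- function(x, ...) {
  nv <- ncol(x) - 3L
  cat(sprintf("VOC feature table: %d samples x %d compounds\n", nrow(x), nv))
  cat("  doses (kGy):", paste(names(table(x$dose_kgy)),
                              table(x$dose_kgy), sep = ":", collapse = "  "), "\n")
  gt <- attr(x, "discriminant")
  if (!is.null(gt)) cat("  ground-truth discriminant compounds:", length(gt), "\n")
  invisible(x)
}

# --- plain-text I/O -----------------------------------------------------------

#' Read a long-format GC-MS peak table
#'
#' Expects the CSV layout `sample_id,compound,rt_min,mz,area`.
#'
#' @param path Path to a CSV file.
#' @return Data frame of peak records.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "compound", "rt_min", "mz", "area")
  if (!all(need %in% names(df))) {
    stop("peak table must have columns ", paste(need, collapse = ","), call. = FALSE)
  }
  if (any(df$rt_min <= 0) || any(df$area < 0) || any(df$mz < 1)) {
    stop("invalid peak record: require rt_min > 0, area >= 0, mz >= 1", call. = FALSE)
  }
  df
}

#' Read an n-alkane ladder from CSV (`carbon,rt_min`)
#'
#' @param path Path to a CSV file.
#' @return An [alkane_ladder()].
#' @export
read_alkane_ladder <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("carbon", "rt_min") %in% names(df))) {
    stop("ladder CSV must have columns carbon,rt_min", call. = FALSE)
  }
  alkane_ladder(df$carbon, df$rt_min)
}

#' Write / read a feature table as CSV
#'
#' The layout is `sample_id,cheese,dose_kgy` followed by one column per
#' compound. Class-map and ground-truth attributes are not serialized here;
#' [run_simulate()] writes them as separate sidecar files.
#'
#' @param x A `voc_table`.
#' @param path Output CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a `voc_table`.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "voc_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "cheese", "dose_kgy")
  if (!all(need %in% names(df))) {
    stop("feature table must start with columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  new_voc_table(df)
}
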