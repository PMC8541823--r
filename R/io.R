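#' Read mEPSP event lists from CSV
#'
#' Expects columns `cell_id`, `amplitude_mV` and optionally `time_s`.
#' Returns one [event_series] per cell.
#'
#' @param path CSV file path.
#' @param duration recording duration in s applied to every cell (or NA).
#' @return Named list of [event_series].
#' @export
read_events_csv <- function(path, duration = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cell_id", "amplitude_mV")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("read_events_csv: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  amp <- suppressWarnings(as.numeric(df$amplitude_mV))
  bad <- which(is.na(amp) & !is.na(df$amplitude_mV) | is.na(df$amplitude_mV))
  if (length(bad))
    stop("read_events_csv: non-numeric amplitude at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  df$amplitude_mV <- amp
  out <- lapply(split(df, df$cell_id), function(d) {
    event_series(d$amplitude_mV, duration = duration,
                 times = if ("time_s" %in% names(d)) d$time_s else NULL,
                 cell_id = d$cell_id[1])
  })
  out
}

#' Write mEPSP events to CSV
#'
#' @param events an [event_series] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  if (inherits(events, "event_series")) events <- list(events)
  rows <- lapply(events, function(ev) {
    d <- data.frame(cell_id = ev$cell_id, amplitude_mV = ev$amplitudes,
                    stringsAsFactors = FALSE)
    if (!is.null(ev$times)) d$time_s <- ev$times
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read larva tracker tables from CSV
#'
#' Reads FIMtrack-style per-frame tables. Wide layout: one larva per file
#' with columns `frame, x, y, area[, spine_length, width]`. Long layout:
#' additionally a `larva_id` column, several larvae per file. Frames must be
#' consecutive (constant spacing).
#'
#' @param path CSV file path.
#' @param fps frame rate (default 12.5).
#' @return Named list of [larva_track].
#' @export
read_track_csv <- function(path, fps = 12.5) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("frame", "x", "y", "area")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("read_track_csv: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"larva_id" %in% names(df)) df$larva_id <- "larva1"
  lapply(split(df, df$larva_id), function(d) {
    d <- d[order(d$frame), ]
    if (nrow(d) > 1 && length(unique(diff(d$frame))) != 1)
      stop("read_track_csv: non-uniform frame spacing for ", d$larva_id[1],
           call. = FALSE)
    larva_track(d$x, d$y, d$area,
                spine_length = if ("spine_length" %in% names(d)) d$spine_length,
                width = if ("width" %in% names(d)) d$width,
                fps = fps, larva_id = d$larva_id[1])
  })
}

#' Write a larva track to CSV (long layout)
#'
#' @param tracks a [larva_track] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(tracks, path) {
  if (inherits(tracks, "larva_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    d <- data.frame(larva_id = tr$larva_id,
                    frame = seq_along(tr$x) - 1L,
                    x = tr$x, y = tr$y, area = tr$area,
                    stringsAsFactors = FALSE)
    if (!is.null(tr$spine_length)) d$spine_length <- tr$spine_length
    if (!is.null(tr$width)) d$width <- tr$width
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a grayscale TIFF as an image scan
#'
#' Reads 2-D images or Z-stacks. Multi-channel (RGB) files are rejected
#' unless a channel is selected.
#'
#' @param path TIFF file path.
#' @param condition condition label for the resulting [image_scan].
#' @param channel channel index for multi-channel files (default NULL).
#' @return An [image_scan]; 3-D stacks keep their planes for [max_project()].
#' @export
read_tiff_scan <- function(path, condition = "HL3", channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tiff::readTIFF(path, all = TRUE)
  pick_channel <- function(m) {
    if (length(dim(m)) == 3) {
      if (is.null(channel))
        stop("read_tiff_scan: multi-channel image, supply channel=",
             call. = FALSE)
      m[, , channel]
    } else m
  }
  planes <- lapply(img, pick_channel)
  px <- if (length(planes) == 1) planes[[1]]
        else array(unlist(planes), dim = c(dim(planes[[1]]), length(planes)))
  image_scan(px, condition = condition)
}

#' Write an image scan to TIFF
#'
#' Intensities are rescaled to `[0, 1]` by the supplied `max_intensity`
#' (TIFF stores normalized grayscale).
#'
#' @param scan an [image_scan] or matrix.
#' @param path output path.
#' @param max_intensity intensity mapped to white (default: image maximum).
#' @return `path`, invisibly.
#' @export
write_tiff_scan <- function(scan, path, max_intensity = NULL) {
  px <- if (inherits(scan, "image_scan")) scan$pixels else scan
  if (is.null(max_intensity)) max_intensity <- max(px, 1e-12)
  tiff::writeTIFF(pmin(px / max_intensity, 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a cross specification from YAML
#'
#' Layout:
#' ```yaml
#' chromosomes:
#'   chr3: {mother: [MI107, TM6B], father: [Df, TM6B]}
#' lethal_rules:
#'   - requires: {TM6B: 2}
#'   - requires: {MI107: 1, Df: 1}
#'     unless: [UAS]
#' ```
#'
#' @param path YAML file path.
#' @return A [cross_spec].
#' @export
read_cross_yaml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  chroms <- lapply(y$chromosomes, function(ch)
    list(mother = as.character(ch$mother), father = as.character(ch$father)))
  rules <- lapply(y$lethal_rules, function(r) {
    list(requires = unlist(r$requires),
         unless = if (!is.null(r$unless)) as.character(r$unless))
  })
  cross_spec(chroms, rules)
}

#' Read a co-IP abundance table from CSV
#'
#' Protein-level layout: `protein_id, gene_symbol, accession` plus one
#' `e<experiment>.<group>` abundance column per cell (empty = missing).
#'
#' @param path CSV file path.
#' @return An [abundance_matrix] at stage `"raw"`.
#' @export
read_abundance_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(df))
    stop("read_abundance_csv: missing protein_id column", call. = FALSE)
  ab_cols <- grep("^e[0-9]+\\.(bait|control)$", names(df), value = TRUE)
  if (length(ab_cols) == 0)
    stop("read_abundance_csv: no e<experiment>.<group> columns", call. = FALSE)
  ab <- as.matrix(df[, ab_cols, drop = FALSE])
  rownames(ab) <- df$protein_id
  abundance_matrix(
    ab,
    gene_symbol = if ("gene_symbol" %in% names(df)) df$gene_symbol
                  else df$protein_id,
    accession = if ("accession" %in% names(df)) df$accession
                else df$protein_id)
}
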