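#' Uniformly sampled multi-channel table
#'
#' The package's container for synchronized time series: a named list of
#' equal-length numeric vectors sharing one sampling rate and start time.
#'
#' @param series Named list of equal-length numeric vectors.
#' @param rate Sampling rate, Hz (> 0).
#' @param start_time Time of the first sample, seconds.
#' @param meta Optional named list of metadata (e.g. segment masses).
#' @return Object of class `channel_table`.
#' @export
channel_table <- function(series, rate, start_time = 0, meta = list()) {
  if (!length(series) || is.null(names(series)) || any(names(series) == ""))
    stop("channel_table: `series` must be a non-empty named list",
         call. = FALSE)
  len <- lengths(series)
  if (length(unique(len)) != 1L)
    stop("channel_table: all series must have equal length", call. = FALSE)
  if (!is.numeric(rate) || rate <= 0)
    stop("channel_table: `rate` must be positive", call. = FALSE)
  structure(list(series = series, rate = as.numeric(rate),
                 start_time = as.numeric(start_time), meta = meta),
            class = "channel_table")
}

#' @export
print.channel_table <- function(x, ...) {
  cat(sprintf("<channel_table> %d channels x %d samples @ %g Hz (t0 = %g s)\n",
              length(x$series), length(x$series[[1L]]), x$rate,
              x$start_time))
  cat("  ", paste(utils::head(names(x$series), 12L), collapse = ", "),
      if (length(x$series) > 12L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Time vector of a channel table
#' @param table A [channel_table()].
#' @return Numeric vector of sample times (s).
#' @export
table_times <- function(table) {
  n <- length(table$series[[1L]])
  table$start_time + (seq_len(n) - 1L) / table$rate
}

forceplate_channels <- c("Fx", "Fy", "Fz", "Mx", "My", "Mz")

# -- TSV dialect: `# key: value` comment header, then a tab-separated
#    header row and numeric body ------------------------------------------

read_channel_tsv <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  hdr_idx <- hdr_idx[hdr_idx == seq_along(hdr_idx)]  # leading block only
  meta <- list()
  for (ln in lines[hdr_idx]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) {
      val <- trimws(m[3L])
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(m[2L])]] <- if (is.na(num)) val else num
    }
  }
  if (is.null(meta$rate))
    stop("format error: header must declare `# rate: <Hz>` in ", path,
         call. = FALSE)
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  body <- body[nzchar(body)]
  if (length(body) < 2L)
    stop("format error: no data rows in ", path, call. = FALSE)
  cols <- strsplit(body[[1L]], "\t", fixed = TRUE)[[1L]]
  cells <- strsplit(body[-1L], "\t", fixed = TRUE)
  if (any(lengths(cells) != length(cols)))
    stop("parse error: ragged row ",
         which(lengths(cells) != length(cols))[1L] + 1L, " in ", path,
         call. = FALSE)
  mat <- matrix(unlist(cells, use.names = FALSE),
                ncol = length(cols), byrow = TRUE)
  series <- stats::setNames(vector("list", length(cols)), cols)
  for (j in seq_along(cols)) {
    v <- suppressWarnings(as.numeric(mat[, j]))
    bad <- which(is.na(v) & nzchar(mat[, j]))
    if (length(bad))
      stop("parse error: non-numeric cell in column `", cols[j],
           "`, data row ", bad[1L], " of ", path, call. = FALSE)
    series[[j]] <- v
  }
  st <- if (is.null(meta$start_time)) 0 else meta$start_time
  channel_table(series, rate = meta$rate, start_time = st, meta = meta)
}

write_channel_tsv <- function(table, path, extra_meta = list()) {
  meta <- utils::modifyList(table$meta, extra_meta)
  meta$rate <- table$rate
  meta$start_time <- table$start_time
  hdr <- vapply(names(meta), function(k)
    sprintf("# %s: %s", k, format(meta[[k]], digits = 17, scientific = FALSE,
                                  trim = TRUE)),
    character(1L))
  body <- do.call(paste, c(lapply(table$series, function(v)
    formatC(v, format = "g", digits = 17)), sep = "\t"))
  writeLines(c(hdr, paste(names(table$series), collapse = "\t"), body), path)
  invisible(path)
}

#' Read or write a force-plate record
#'
#' TSV with a `# key: value` comment header declaring at least `rate` (Hz),
#' then columns `Fx Fy Fz Mx My Mz` (N and N·m).
#'
#' @param path File path.
#' @return `read_forceplate()`: a [channel_table()] with exactly the six
#'   force/moment channels.
#' @export
read_forceplate <- function(path) {
  tab <- read_channel_tsv(path)
  missing <- setdiff(forceplate_channels, names(tab$series))
  if (length(missing))
    stop("format error: force-plate file missing channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab$series <- tab$series[forceplate_channels]
  tab
}

#' @rdname read_forceplate
#' @param table A [channel_table()] with the six force/moment channels.
#' @export
write_forceplate <- function(table, path) {
  missing <- setdiff(forceplate_channels, names(table$series))
  if (length(missing))
    stop("format error: cannot write force-plate table without: ",
         paste(missing, collapse = ", "), call. = FALSE)
  write_channel_tsv(table, path)
}

#' Read or write a segment-kinematics record
#'
#' TSV with `<segment>.{x,y,z}` centroid columns (m) plus chest-marker
#' columns; the comment header declares `rate`, per-segment masses as
#' `mass.<segment>` and the subject's `body_mass` and `height`. Masses must
#' sum to the declared body mass within 1e-6 relative tolerance.
#'
#' @param path File path.
#' @return `read_kinematics()`: a [channel_table()] whose `meta` carries the
#'   segment masses and anthropometry.
#' @export
read_kinematics <- function(path) {
  tab <- read_channel_tsv(path)
  mkeys <- grep("^mass\\.", names(tab$meta), value = TRUE)
  if (!length(mkeys))
    stop("format error: kinematics header declares no `mass.<segment>` keys",
         call. = FALSE)
  masses <- stats::setNames(unlist(tab$meta[mkeys]), sub("^mass\\.", "", mkeys))
  if (!is.null(tab$meta$body_mass)) {
    rel <- abs(sum(masses) - tab$meta$body_mass) / tab$meta$body_mass
    if (rel > 1e-6)
      stop("validation error: segment masses sum to ",
           signif(sum(masses), 8), " kg but declared body mass is ",
           tab$meta$body_mass, " kg", call. = FALSE)
  }
  tab$meta$seg_masses <- masses
  tab
}

#' @rdname read_kinematics
#' @param table A [channel_table()].
#' @param seg_masses Named vector of segment masses (kg).
#' @param body_mass,height Subject anthropometry written to the header.
#' @export
write_kinematics <- function(table, path, seg_masses, body_mass, height) {
  extra <- as.list(stats::setNames(seg_masses,
                                   paste0("mass.", names(seg_masses))))
  extra$body_mass <- body_mass
  extra$height <- height
  tab <- table
  tab$meta$seg_masses <- NULL
  write_channel_tsv(tab, path, extra_meta = extra)
}

#' Read or write heel-strike events
#'
#' One event time (s) per line; comma-separated values on a line are also
#' accepted. Times must be strictly increasing.
#'
#' @param path File path.
#' @return `read_events()`: numeric vector of strictly increasing times.
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  ev <- suppressWarnings(as.numeric(unlist(strsplit(lines, ","))))
  if (anyNA(ev))
    stop("parse error: non-numeric event time in ", path, call. = FALSE)
  if (is.unsorted(ev, strictly = TRUE))
    stop("validation error: event times must be strictly increasing",
         call. = FALSE)
  ev
}

#' @rdname read_events
#' @param events Strictly increasing numeric vector of times (s).
#' @export
write_events <- function(events, path) {
  if (is.unsorted(events, strictly = TRUE))
    stop("validation error: event times must be strictly increasing",
         call. = FALSE)
  writeLines(formatC(events, format = "g", digits = 17), path)
  invisible(path)
}

#' Write / read a full trial to a directory
#'
#' Convenience bundle: `forceplate.tsv`, `kinematics.tsv`, `events.txt` and
#' a `trial.json` sidecar with anthropometry and condition.
#'
#' @param trial A `wbi_trial`.
#' @param dir Directory (created if needed).
#' @return `read_trial()`: a `wbi_trial`.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_forceplate(trial$grf, file.path(dir, "forceplate.tsv"))
  write_kinematics(trial$kin, file.path(dir, "kinematics.tsv"),
                   trial$seg_masses, trial$mass, trial$height)
  write_events(trial$events, file.path(dir, "events.txt"))
  side <- list(height = trial$height, mass = trial$mass,
               belt_offset_h = trial$belt_offset_h,
               condition = trial$condition)
  if (!is.null(trial$config))
    side$config <- unclass(trial$config)
  jsonlite::write_json(side, file.path(dir, "trial.json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(dir)
}

#' @rdname write_trial
#' @export
read_trial <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "trial.json"),
                              simplifyVector = TRUE)
  kin <- read_kinematics(file.path(dir, "kinematics.tsv"))
  structure(list(
    grf = read_forceplate(file.path(dir, "forceplate.tsv")),
    kin = kin,
    seg_masses = kin$meta$seg_masses,
    events = read_events(file.path(dir, "events.txt")),
    height = side$height, mass = side$mass,
    belt_offset_h = side$belt_offset_h,
    condition = side$condition, config = NULL
  ), class = "wbi_trial")
}

#' Resample a channel table onto a uniform target grid
#'
#' Linear interpolation onto a grid at `target_rate` spanning the table's
#' own time support. Intended for decimating an already low-pass-filtered
#' signal onto the common analysis grid; upsampling must be requested
#' explicitly.
#'
#' @param table A [channel_table()].
#' @param target_rate Target rate, Hz.
#' @param allow_upsample Permit `target_rate` above the source rate.
#' @return A [channel_table()] at `target_rate`.
#' @export
resample_to_grid <- function(table, target_rate, allow_upsample = FALSE) {
  if (!inherits(table, "channel_table") || !length(table$series))
    stop("resample_to_grid: empty or invalid table", call. = FALSE)
  if (!is.numeric(target_rate) || target_rate <= 0)
    stop("resample_to_grid: `target_rate` must be positive", call. = FALSE)
  if (target_rate > table$rate && !allow_upsample)
    stop("resample_to_grid: upsampling from ", table$rate, " to ",
         target_rate, " Hz requires `allow_upsample = TRUE`", call. = FALSE)
  if (target_rate == table$rate) return(table)
  t_src <- table_times(table)
  t_end <- t_src[length(t_src)]
  n_new <- floor((t_end - table$start_time) * target_rate) + 1L
  t_new <- table$start_time + (seq_len(n_new) - 1L) / target_rate
  series <- lapply(table$series, function(v)
    stats::approx(t_src, v, xout = t_new, rule = 2)$y)
  channel_table(series, rate = target_rate, start_time = table$start_time,
                meta = table$meta)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward 4th-order Butterworth, the standard gait-lab smoothing
#' step. Defaults used by the pipeline: 15 Hz for force-plate channels,
#' 6 Hz for kinematics.
#'
#' @param x Numeric vector.
#' @param rate Sampling rate, Hz.
#' @param cutoff Cut-off frequency, Hz (must be below the Nyquist rate).
#' @param order Filter order (doubled in effect by the two passes).
#' @return Filtered vector, same length.
#' @export
lowpass_filter <- function(x, rate, cutoff, order = 4L) {
  if (cutoff <= 0 || cutoff >= rate / 2)
    stop("lowpass_filter: `cutoff` must lie in (0, rate/2)", call. = FALSE)
  bf <- signal::butter(order, 2 * cutoff / rate, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

filter_table <- function(table, cutoff, order = 4L) {
  table$series <- lapply(table$series, lowpass_filter,
                         rate = table$rate, cutoff = cutoff, order = order)
  table
}

#' Serialize a fitted index model to versioned JSON
#'
#' Round-trips every model component at full double precision.
#'
#' @param model A `wbi_model` from [fit_index()].
#' @param path Output path.
#' @return `read_index_model()`: a `wbi_model`.
#' @export
write_index_model <- function(model, path) {
  payload <- list(
    format = "wbi-model", version = 1L,
    features = model$features,
    height = model$height, mass = model$mass, g = model$g,
    center = model$center, scale = model$scale,
    coefficients = model$coefficients,   # retained components x features
    eigenvalues = model$eigenvalues,
    n_retained = model$n_retained,
    weights = model$weights,
    weight_norm = model$weight_norm,
    orientation = model$orientation,
    cum_contribution = model$cum_contribution,
    kmo = model$kmo,
    threshold = model$threshold,
    provenance = model$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_index_model
#' @export
read_index_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "wbi-model")
    stop("format error: not a wbi model file: ", path, call. = FALSE)
  coef <- p$coefficients
  if (is.null(dim(coef)))
    coef <- matrix(coef, nrow = p$n_retained,
                   dimnames = list(NULL, p$features))
  colnames(coef) <- p$features
  structure(list(
    features = p$features, height = p$height, mass = p$mass, g = p$g,
    center = stats::setNames(as.numeric(p$center), p$features),
    scale = stats::setNames(as.numeric(p$scale), p$features),
    coefficients = coef,
    eigenvalues = as.numeric(p$eigenvalues),
    n_retained = as.integer(p$n_retained),
    weights = as.numeric(p$weights),
    weight_norm = p$weight_norm,
    orientation = as.numeric(p$orientation),
    cum_contribution = as.numeric(p$cum_contribution),
    kmo = if (is.null(p$kmo)) NA_real_ else as.numeric(p$kmo),
    threshold = as.numeric(p$threshold),
    provenance = p$provenance
  ), class = "wbi_model")
}
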