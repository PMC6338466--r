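# File formats: LAMMPS-style text dumps, tidy CSV series, JSON chronology
# reports.  All text output uses '.' decimals and a fixed column order;
# coordinates round-trip at 9 significant digits.

#' Write a trajectory as a LAMMPS-style text dump
#'
#' One `ITEM:`-delimited block per frame with columns
#' `id mol type xu yu` (unwrapped coordinates, 9 significant digits).
#' The `mol` column is the filament id.  Frame timesteps are the production
#' step indices.
#'
#' @param traj an `mt_traj` (or anything with `frames`, `steps`,
#'   `filament`, and `params$box_edge`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dump <- function(traj, path) {
  n <- dim(traj$frames)[2]
  Lb <- traj$params$box_edge
  con <- file(path, "w")
  on.exit(close(con))
  ids <- seq_len(n)
  for (f in seq_along(traj$steps)) {
    x <- matrix(traj$frames[f, , ], ncol = 2)
    writeLines(c(
      "ITEM: TIMESTEP",
      format(traj$steps[f]),
      "ITEM: NUMBER OF ATOMS",
      format(n),
      "ITEM: BOX BOUNDS pp pp pp",
      sprintf("%.9g %.9g", 0, Lb),
      sprintf("%.9g %.9g", 0, Lb),
      "-0.5 0.5",
      "ITEM: ATOMS id mol type xu yu",
      sprintf("%d %d 1 %.9g %.9g", ids, traj$filament, x[, 1], x[, 2])
    ), con)
  }
  invisible(path)
}

#' Read a LAMMPS-style text dump
#'
#' Parses `ITEM:`-delimited frames; columns are mapped by the header names,
#' so extra columns (e.g. a constant `z`/`zu`) are tolerated and ignored,
#' while missing required columns (`id`, `mol`, `xu`, `yu`) are errors.
#' Duplicate atom ids and non-monotone timesteps are parse errors naming
#' the offending line.
#'
#' @param path dump file.
#' @param params optional `mt_params`; when given, frame times are
#'   converted to `tauR` using its timestep and the box edge is checked.
#' @return an `mt_traj` (energies/motor counts absent; times in `tauR`
#'   when `params` is given, otherwise in steps).
#' @export
read_dump <- function(path, params = NULL) {
  if (!file.exists(path)) stop("dump file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  nlin <- length(lines)
  frames <- list()
  steps <- integer(0)
  fil <- NULL
  box <- NA_real_
  perr <- function(msg, at) {
    stop(sprintf("dump parse error at line %d: %s", at, msg), call. = FALSE)
  }
  while (i <= nlin) {
    if (!startsWith(lines[i], "ITEM: TIMESTEP")) {
      perr("expected 'ITEM: TIMESTEP'", i)
    }
    step <- suppressWarnings(as.integer(lines[i + 1]))
    if (is.na(step)) perr("bad timestep value", i + 1)
    if (length(steps) && step <= steps[length(steps)]) {
      perr("non-monotone timestep", i + 1)
    }
    if (!startsWith(lines[i + 2], "ITEM: NUMBER OF ATOMS")) {
      perr("expected 'ITEM: NUMBER OF ATOMS'", i + 2)
    }
    nat <- suppressWarnings(as.integer(lines[i + 3]))
    if (is.na(nat) || nat < 1) perr("bad atom count", i + 3)
    if (!startsWith(lines[i + 4], "ITEM: BOX BOUNDS")) {
      perr("expected 'ITEM: BOX BOUNDS'", i + 4)
    }
    bb <- strsplit(trimws(lines[i + 5]), "\\s+")[[1]]
    box <- as.numeric(bb[2]) - as.numeric(bb[1])
    hdr_at <- i + 8L
    if (!startsWith(lines[hdr_at], "ITEM: ATOMS")) {
      perr("expected 'ITEM: ATOMS'", hdr_at)
    }
    cols <- strsplit(trimws(sub("ITEM: ATOMS", "", lines[hdr_at])),
                     "\\s+")[[1]]
    need <- c("id", "mol", "xu", "yu")
    missing_cols <- setdiff(need, cols)
    if (length(missing_cols)) {
      perr(paste("missing required column(s):",
                 paste(missing_cols, collapse = ", ")), hdr_at)
    }
    body <- lines[hdr_at + seq_len(nat)]
    tab <- utils::read.table(text = body, col.names = cols,
                             colClasses = "numeric")
    if (anyDuplicated(tab$id)) perr("duplicate atom id", hdr_at + 1)
    ord <- order(tab$id)
    tab <- tab[ord, ]
    if (!all(tab$id == seq_len(nat))) {
      perr("atom ids not contiguous from 1", hdr_at + 1)
    }
    if (is.null(fil)) {
      fil <- as.integer(tab$mol)
    } else if (!identical(as.integer(tab$mol), fil)) {
      perr("molecule assignment changed between frames", hdr_at + 1)
    }
    frames[[length(frames) + 1L]] <- cbind(tab$xu, tab$yu)
    steps <- c(steps, step)
    i <- hdr_at + nat + 1L
  }
  n <- nrow(frames[[1]])
  arr <- array(0, dim = c(length(frames), n, 2))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  if (is.null(params)) {
    nb <- n / length(unique(fil))
    params <- make_params(list(nf = length(unique(fil)), nb = nb, Lb = box))
    times <- as.numeric(steps)
  } else {
    if (abs(box - params$box_edge) > 1e-6 * box) {
      stop("dump box edge does not match params", call. = FALSE)
    }
    times <- steps * params$timestep / params$rotation_time
  }
  rank <- stats::ave(seq_len(n), fil, FUN = seq_along)
  structure(list(
    frames = arr, steps = steps, times = times, filament = fil,
    rank = as.integer(rank), params = params,
    energies = NULL, motor_counts = NULL, seed = NA_integer_,
    schedule = NULL
  ), class = "mt_traj")
}

#' Write a correlation series as tidy CSV
#'
#' @param series an `mt_corr`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  df <- as.data.frame(series)
  df$kind <- attr(series, "kind")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a chronology report as JSON
#'
#' Emits the five timescales with confidence intervals and resolution
#' flags, plus the parameter snapshot, as structured text.
#'
#' @param report an `mt_chronology`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chronology_json <- function(report, path) {
  entry <- function(e) {
    list(time_tauR = e$time, ci = e$ci, resolved = e$resolved,
         reason = if (is.null(e$reason)) NA else e$reason)
  }
  obj <- list(
    tau_N_min = entry(report$tau_n_min),
    tau_Q_half = entry(report$tau_q_half),
    tau_star = entry(report$tau_star),
    tau_N_max = entry(report$tau_n_max),
    tau_r = entry(report$tau_r),
    ordering_ok = report$ordering_ok,
    params = report$params
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
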