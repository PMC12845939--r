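#' Write / read a session trace as CSV
#'
#' Columnar text format: `t_ms, pupil_l_mm, pupil_r_mm, gaze_x_deg,
#' gaze_y_deg, valid` (UTF-8, dot decimal); single-eye traces use
#' `pupil_mm`.
#'
#' @param trace trace data frame.
#' @param path file path.
#' @return the path (write) or the trace data frame (read).
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  tr <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!"t_ms" %in% names(tr)) stop("trace file lacks a t_ms column")
  tr$valid <- as.logical(tr$valid)
  tr
}

#' Write / read a block schedule as JSON
#'
#' @param schedule a [block_schedule()] data frame.
#' @param path file path.
#' @param participant_id,state optional session metadata.
#' @return the path (write) or a list `participant_id`, `state`,
#'   `schedule` (read).
#' @export
write_schedule_json <- function(schedule, path, participant_id = NA,
                                state = NA) {
  obj <- list(participant_id = participant_id, state = state,
              blocks = as.data.frame(schedule))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  sch <- obj$blocks
  class(sch) <- c("block_schedule", "data.frame")
  list(participant_id = obj$participant_id, state = obj$state, schedule = sch)
}

#' Write / read an eye image as plain PGM (P2)
#'
#' Plain-text portable greymap, maxval 255; the ground-truth circle geometry
#' travels in a JSON sidecar (same path with extension `.json`) when the
#' image carries one.
#'
#' @param image an `eye_image` or intensity matrix in `[0, 1]`.
#' @param path file path (`.pgm`).
#' @param sidecar also write the ground-truth sidecar.
#' @return the path (write) or an `eye_image` (read; `truth` is `NULL`
#'   without a sidecar).
#' @export
write_pgm <- function(image, path, sidecar = TRUE) {
  img <- if (inherits(image, "eye_image")) image$pixels else image
  v <- round(clamp(img, 0, 1) * 255)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  write(t(v), con, ncolumns = ncol(img))
  if (sidecar && inherits(image, "eye_image") && !is.null(image$truth))
    jsonlite::write_json(image$truth, sub("\\.pgm$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (txt[1] != "P2") stop("only plain (P2) PGM is supported")
  nc <- as.integer(txt[2]); nr <- as.integer(txt[3]); maxv <- as.numeric(txt[4])
  v <- as.numeric(txt[-(1:4)])
  if (length(v) != nr * nc) stop("corrupt PGM payload")
  img <- matrix(v, nr, nc, byrow = TRUE) / maxv
  side <- sub("\\.pgm$", ".json", path)
  truth <- if (file.exists(side)) jsonlite::fromJSON(side) else NULL
  structure(list(pixels = img, truth = truth), class = "eye_image")
}

# -- iris-code gallery (JSON lines, hex-packed big-endian bits) --------------

#' Hex packing of iris-code bits
#'
#' Big-endian bit order: the first bit is the most significant bit of the
#' first hex digit; codes are left-padded to a multiple of 4 bits.
#'
#' @param bits 0/1 vector.
#' @return hex string.
#' @export
code_to_hex <- function(bits) {
  pad <- (4 - length(bits) %% 4) %% 4
  b <- c(rep(0L, pad), as.integer(bits))
  nib <- matrix(b, nrow = 4)
  vals <- 8 * nib[1, ] + 4 * nib[2, ] + 2 * nib[3, ] + nib[4, ]
  paste(substring("0123456789abcdef", vals + 1, vals + 1), collapse = "")
}

#' @rdname code_to_hex
#' @param hex hex string.
#' @param n_bits code length (trailing `n_bits` bits are taken).
#' @return 0/1 integer vector.
#' @export
hex_to_code <- function(hex, n_bits) {
  vals <- strtoi(strsplit(tolower(hex), "")[[1]], base = 16L)
  bits <- as.integer(vapply(vals, function(v)
    c(v %/% 8 %% 2, v %/% 4 %% 2, v %/% 2 %% 2, v %% 2), numeric(4)))
  utils::tail(bits, n_bits)
}

#' Write / read an iris-code gallery (JSON lines)
#'
#' One record per line: `{identity_id, n_bits, n_radial, n_angular,
#' code_hex}`.
#'
#' @param codes list of [iris_code()]s.
#' @param path gallery file path.
#' @return the path (write) or a list of [iris_code()]s (read).
#' @export
write_gallery <- function(codes, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (cd in codes) {
    rec <- list(identity_id = cd$identity %||% NA, n_bits = length(cd$bits),
                n_radial = cd$n_radial, n_angular = cd$n_angular,
                code_hex = code_to_hex(cd$bits))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_gallery
#' @export
read_gallery <- function(path) {
  lapply(readLines(path, encoding = "UTF-8"), function(l) {
    rec <- jsonlite::fromJSON(l)
    iris_code(hex_to_code(rec$code_hex, rec$n_bits),
              n_radial = rec$n_radial, n_angular = rec$n_angular,
              identity = rec$identity_id)
  })
}

#' Write / read baseline profiles as JSON
#'
#' @param profile a [build_baseline()] result.
#' @param path file path.
#' @return the path (write) or a `baseline_profile` data frame (read).
#' @export
write_profiles_json <- function(profile, path) {
  jsonlite::write_json(as.data.frame(profile), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_profiles_json
#' @export
read_profiles_json <- function(path) {
  p <- jsonlite::fromJSON(path)
  structure(p, class = c("baseline_profile", "data.frame"))
}

#' Write / read a feature table as CSV
#'
#' Columns: `participant_id, session_id, stimulus_idx, valence, PDA, CL,
#' CL_censored, PDV, FD, SV, SA, GDE, EMA` (additional columns pass
#' through).
#'
#' @param features feature data frame.
#' @param path file path.
#' @return the path (write) or the data frame (read).
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  f <- utils::read.csv(path, fileEncoding = "UTF-8")
  if ("CL_censored" %in% names(f)) f$CL_censored <- as.logical(f$CL_censored)
  f
}
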