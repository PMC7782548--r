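#' Read a COLVAR-style whitespace table
#'
#' The dialect used across the enhanced-sampling ecosystem: a first line
#' `#! FIELDS time cv1 cv2 ...` naming the columns, then one whitespace-
#' separated numeric row per record. Additional `#!` lines (e.g. `#! SET ...`)
#' are kept as attributes.
#'
#' @param path file path.
#' @return data.frame with the named columns, in file order. Attribute
#'   `colvar_set` holds any `#! SET key value` pairs.
#' @export
read_colvar <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^#!\\s+FIELDS\\s+", lines[1]))
    stop("not a COLVAR file: first line must be '#! FIELDS ...' in ", path)
  fields <- strsplit(sub("^#!\\s+FIELDS\\s+", "", lines[1]), "\\s+")[[1]]
  set_lines <- grep("^#!\\s+SET\\s+", lines, value = TRUE)
  sets <- list()
  for (sl in set_lines) {
    kv <- strsplit(sub("^#!\\s+SET\\s+", "", sl), "\\s+")[[1]]
    if (length(kv) >= 2) sets[[kv[1]]] <- paste(kv[-1], collapse = " ")
  }
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  rows <- lines[body_idx]
  if (length(rows) == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, length(fields)))
    names(out) <- fields
    attr(out, "colvar_set") <- sets
    return(out)
  }
  toks <- strsplit(trimws(rows), "\\s+")
  nf <- lengths(toks)
  if (any(nf != length(fields))) {
    bad <- body_idx[which(nf != length(fields))[1]]
    stop("ragged COLVAR row at line ", bad, " of ", path,
         ": expected ", length(fields), " fields, found ", nf[which(nf != length(fields))[1]])
  }
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    bad_row <- which(vapply(toks, function(t) anyNA(suppressWarnings(as.numeric(t))), logical(1)))[1]
    stop("non-numeric value in COLVAR row at line ", body_idx[bad_row], " of ", path)
  }
  out <- as.data.frame(matrix(vals, ncol = length(fields), byrow = TRUE))
  names(out) <- fields
  attr(out, "colvar_set") <- sets
  out
}

#' Write a COLVAR-style whitespace table
#'
#' @param x data.frame of numeric columns.
#' @param path output path.
#' @param set named character vector/list written as `#! SET key value` lines
#'   (used e.g. to embed the configuration hash in artifacts).
#' @param digits significant digits (default 12; round-trips through
#'   [read_colvar()] losslessly at that precision).
#' @export
write_colvar <- function(x, path, set = NULL, digits = 12) {
  stopifnot(is.data.frame(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(x), collapse = " ")), con)
  for (k in names(set))
    writeLines(paste("#! SET", k, set[[k]]), con)
  if (nrow(x) > 0) {
    m <- vapply(x, function(col) formatC(col, digits = digits, format = "g"),
                character(nrow(x)))
    if (nrow(x) == 1L) m <- matrix(m, nrow = 1)
    writeLines(apply(m, 1, paste, collapse = " "), con)
  }
  invisible(path)
}

# -- extended-XYZ frames -------------------------------------------------------

new_frame <- function(elements, xyz, box = c(3, 3, 3),
                      axis = list(origin = c(0, 0, -0.8), dir = c(0, 0, 1)),
                      comment = "") {
  stopifnot(length(elements) == nrow(xyz), ncol(xyz) == 3)
  list(elements = as.character(elements), xyz = xyz, box = box, axis = axis,
       comment = comment)
}

parse_kv_comment <- function(comment) {
  out <- list()
  m <- gregexpr('([A-Za-z_]+)="([^"]*)"', comment)[[1]]
  if (m[1] == -1) return(out)
  for (i in seq_along(m)) {
    piece <- substr(comment, m[i], m[i] + attr(m, "match.length")[i] - 1)
    key <- sub('=.*$', '', piece)
    val <- gsub('^.*="|"$', '', piece)
    out[[key]] <- val
  }
  out
}

#' Read extended-XYZ frames
#'
#' Each block: an atom-count line, a comment line carrying
#' `box="lx ly lz" axis_origin="x y z" axis_dir="x y z"` key-value pairs, then
#' one `element x y z` line per atom (coordinates in nm). Frames in one file
#' may have different atom counts.
#'
#' @param path file path.
#' @return list of frames (class `xyz_frames`); each frame has `elements`,
#'   `xyz` (n x 3 matrix, nm), `box`, `axis` (`origin`, `dir`) and `comment`.
#' @export
read_xyz_frames <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("bad atom-count line ", i, " in ", path)
    if (i + 1L + n > length(lines))
      stop("frame starting at line ", i, " declares ", n,
           " atoms but the file ends early (count mismatch)")
    comment <- lines[i + 1L]
    kv <- parse_kv_comment(comment)
    atoms <- lines[i + 1L + seq_len(n)]
    toks <- strsplit(trimws(atoms), "\\s+")
    if (any(lengths(toks) < 4))
      stop("malformed atom line in frame starting at line ", i, " of ", path)
    el <- vapply(toks, `[[`, character(1), 1)
    xyz <- matrix(as.numeric(unlist(lapply(toks, function(t) t[2:4]))),
                  ncol = 3, byrow = TRUE)
    if (anyNA(xyz)) stop("non-numeric coordinate in frame starting at line ", i)
    num3 <- function(key, default) {
      if (is.null(kv[[key]])) default
      else as.numeric(strsplit(trimws(kv[[key]]), "\\s+")[[1]])
    }
    frames[[length(frames) + 1L]] <- new_frame(
      el, xyz,
      box = num3("box", c(NA, NA, NA)),
      axis = list(origin = num3("axis_origin", c(0, 0, 0)),
                  dir = num3("axis_dir", c(0, 0, 1))),
      comment = comment
    )
    i <- i + 2L + n
  }
  if (length(frames) == 0L)
    warning("no frames found in ", path)
  structure(frames, class = "xyz_frames")
}

#' Write extended-XYZ frames
#'
#' @param frames list of frames as returned by [read_xyz_frames()] or
#'   [toy_host_guest_frames()].
#' @param path output path.
#' @export
write_xyz_frames <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt3 <- function(v) paste(formatC(v, digits = 10, format = "g"), collapse = " ")
  for (fr in frames) {
    writeLines(as.character(nrow(fr$xyz)), con)
    writeLines(sprintf('box="%s" axis_origin="%s" axis_dir="%s"',
                       fmt3(fr$box), fmt3(fr$axis$origin), fmt3(fr$axis$dir)), con)
    writeLines(sprintf("%s %s %s %s", fr$elements,
                       formatC(fr$xyz[, 1], digits = 10, format = "g"),
                       formatC(fr$xyz[, 2], digits = 10, format = "g"),
                       formatC(fr$xyz[, 3], digits = 10, format = "g")), con)
  }
  invisible(path)
}
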