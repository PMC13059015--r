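#' Read a multi-frame XYZ trajectory
#'
#' Parses a (possibly extended) XYZ file: each frame is an atom-count line, a
#' comment line, then one `symbol x y z` line per atom. A per-frame energy is
#' recovered from the comment line when it carries an `energy=` or `E=`
#' key=value token, or, failing that, a bare trailing float; dialects vary
#' across NEB drivers, so the first match wins. Frames may have differing
#' atom counts (they are parsed independently).
#'
#' @param path file path.
#' @return list of [AtomicConfiguration-class], one per frame (empty list for
#'   an empty file).
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' writeLines(c("2", "energy=-1.5", "H 0 0 0", "H 0.74 0 0"), f)
#' traj <- readXYZTrajectory(f)
#' potentialEnergy(traj[[1]])
#' @export
readXYZTrajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # trailing blank lines are tolerated
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 0L)
      stop("malformed frame header at line ", i, ": ", sQuote(lines[i]))
    if (i + 1L + n > length(lines))
      stop("truncated frame starting at line ", i,
           ": expected ", n, " atom lines")
    comment <- lines[i + 1L]
    atoms <- lines[(i + 2L):(i + 1L + n)]
    if (n == 0L) atoms <- character()
    toks <- strsplit(trimws(atoms), "\\s+")
    bad <- which(vapply(toks, length, 1L) < 4L)
    if (length(bad))
      stop("malformed atom line at line ", i + 1L + bad[1L])
    sym <- vapply(toks, `[[`, "", 1L)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (n > 0L && any(is.na(xyz)))
      stop("non-numeric coordinate in frame starting at line ", i)
    out[[length(out) + 1L]] <- atomicConfiguration(
      sym, if (n > 0L) xyz else matrix(numeric(), 0L, 3L),
      energy = .parseCommentEnergy(comment), tag = comment)
    i <- i + 2L + n
  }
  out
}

# energy=<v> or E=<v> token, else a bare trailing float; first match wins
.parseCommentEnergy <- function(comment) {
  toks <- strsplit(trimws(comment), "\\s+")[[1]]
  for (tk in toks) {
    m <- regmatches(tk, regexec("^(?:energy|E)=([-+0-9.eEdD]+)$", tk))[[1]]
    if (length(m) == 2L) {
      v <- suppressWarnings(as.numeric(gsub("[dD]", "e", m[2])))
      if (!is.na(v)) return(v)
    }
  }
  if (length(toks)) {
    v <- suppressWarnings(as.numeric(toks[length(toks)]))
    if (!is.na(v)) return(v)
  }
  NA_real_
}

#' Write a multi-frame XYZ trajectory
#'
#' Inverse of [readXYZTrajectory()]; energies are stored as `energy=` tokens
#' on the comment line. Positions are printed with 12 significant digits so a
#' read/write round trip is lossless well beyond 1e-10 Angstrom.
#'
#' @param frames non-empty list of [AtomicConfiguration-class] objects (or a
#'   single configuration).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeXYZTrajectory <- function(frames, path) {
  if (is(frames, "AtomicConfiguration")) frames <- list(frames)
  if (!length(frames)) stop("frames must be non-empty")
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nAtoms(fr)
    if (n == 0L) stop("cannot write a zero-atom frame")
    e <- potentialEnergy(fr)
    comment <- if (is.na(e)) "frame" else sprintf("energy=%.12g", e)
    writeLines(as.character(n), con)
    writeLines(comment, con)
    writeLines(sprintf("%s %.12f %.12f %.12f", elementSymbols(fr),
                       positions(fr)[, 1], positions(fr)[, 2],
                       positions(fr)[, 3]), con)
  }
  invisible(path)
}

#' Read a per-image path data table
#'
#' Reads a whitespace-delimited numeric table of per-image path records (an
#' eOn-style `.dat` file). Lines starting with `#` are skipped. By
#' convention the tangential force component lives in column 3 of such
#' files; the column layout here defaults to
#' (image index, reaction coordinate, energy, parallel force) but every
#' column index is configurable because dialects differ.
#'
#' @param path file path.
#' @param force_column column holding the tangential force F_par.
#' @param index_column,coordinate_column,energy_column remaining columns.
#' @param one_based logical; when `FALSE`, column indices are 0-based.
#' @return data.frame with columns `image_index`, `reaction_coordinate`,
#'   `energy`, `parallel_force` and `iteration` (snapshot id; a new snapshot
#'   starts wherever `image_index` does not increase).
#' @export
readPathTable <- function(path, force_column = 4L, index_column = 1L,
                          coordinate_column = 2L, energy_column = 3L,
                          one_based = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  rowno <- which(keep)
  cols <- c(index = index_column, coordinate = coordinate_column,
            energy = energy_column, force = force_column)
  if (!one_based) cols <- cols + 1L
  if (any(cols < 1L)) stop("column indices must be positive")
  if (!length(lines)) {
    return(data.frame(image_index = integer(), reaction_coordinate = numeric(),
                      energy = numeric(), parallel_force = numeric(),
                      iteration = integer()))
  }
  toks <- strsplit(trimws(lines), "\\s+")
  vals <- matrix(NA_real_, length(toks), max(cols))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) < max(cols))
      stop("row ", rowno[i], " has ", length(tk),
           " columns; column ", max(cols), " requested")
    v <- suppressWarnings(as.numeric(tk[seq_len(max(cols))]))
    if (anyNA(v[cols])) {
      badcol <- cols[which(is.na(v[cols]))[1L]]
      stop("non-numeric value at row ", rowno[i], ", column ", badcol)
    }
    vals[i, ] <- v
  }
  idx <- as.integer(vals[, cols["index"]])
  iteration <- cumsum(c(TRUE, diff(idx) <= 0)) - 1L
  data.frame(
    image_index = idx,
    reaction_coordinate = vals[, cols["coordinate"]],
    energy = vals[, cols["energy"]],
    parallel_force = vals[, cols["force"]],
    iteration = iteration
  )
}

#' Write a projection table
#'
#' Writes projected points as a tab-separated table with a commented header:
#' columns `r`, `p`, `s`, `d`, `energy`, `grad_r`, `grad_p`. Values are
#' printed with enough digits for a 1e-10 round trip via
#' [readProjectionTable()].
#'
#' @param points data.frame of projected points (missing columns are written
#'   as `NA`).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeProjectionTable <- function(points, path) {
  cols <- c("r", "p", "s", "d", "energy", "grad_r", "grad_p")
  df <- as.data.frame(points)
  for (cl in cols) if (is.null(df[[cl]])) df[[cl]] <- rep(NA_real_, nrow(df))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(cols, collapse = "\t")), con)
  if (nrow(df)) {
    fmt <- function(v) sprintf("%.12g", v)
    body <- do.call(paste, c(lapply(df[cols], fmt), sep = "\t"))
    body <- gsub("NA", "nan", body, fixed = TRUE)
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname writeProjectionTable
#' @export
readProjectionTable <- function(path) {
  cols <- c("r", "p", "s", "d", "energy", "grad_r", "grad_p")
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = cols, na.strings = c("nan", "NA"),
                          colClasses = "numeric")
  if (!nrow(df)) df <- as.data.frame(stats::setNames(
    rep(list(numeric()), length(cols)), cols))
  df
}

#' Read a single reference structure
#'
#' Accepts either a (single- or multi-frame) XYZ file, of which the first
#' frame is used, or a minimal eOn-style `.con` file. The `.con` dialect
#' supported is deliberately small: 9 header lines (comments, cell lengths,
#' cell angles, two filler lines, component count), the per-component atom
#' counts and masses, then for each component an element line, a
#' "Coordinates of Component" line, and Cartesian `x y z [fixed] [index]`
#' rows. Only the Cartesian block is interpreted.
#'
#' @param path file path ending in `.xyz`/`.con` (anything not `.con` is
#'   parsed as XYZ).
#' @return an [AtomicConfiguration-class].
#' @export
readReferenceStructure <- function(path) {
  if (grepl("\\.con$", path, ignore.case = TRUE)) return(.readCon(path))
  fr <- readXYZTrajectory(path)
  if (!length(fr)) stop("no frames in ", path)
  fr[[1]]
}

.readCon <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 11L) stop("truncated .con file: ", path)
  ncomp <- suppressWarnings(as.integer(trimws(lines[9])))
  if (is.na(ncomp) || ncomp < 1L)
    stop("cannot parse component count at .con line 9")
  counts <- suppressWarnings(as.integer(strsplit(trimws(lines[10]), "\\s+")[[1]]))
  if (anyNA(counts) || length(counts) != ncomp)
    stop("cannot parse per-component atom counts at .con line 10")
  i <- 12L  # line 11 is the per-component mass list
  sym <- character(); pos <- NULL
  for (k in seq_len(ncomp)) {
    el <- trimws(lines[i])
    i <- i + 2L  # skip "Coordinates of Component" line
    block <- lines[i:(i + counts[k] - 1L)]
    xyz <- t(vapply(strsplit(trimws(block), "\\s+"),
                    function(tk) as.numeric(tk[1:3]), numeric(3)))
    if (any(is.na(xyz)))
      stop("non-numeric coordinates in .con component ", k)
    sym <- c(sym, rep(el, counts[k]))
    pos <- rbind(pos, xyz)
    i <- i + counts[k]
  }
  atomicConfiguration(sym, pos, tag = trimws(lines[1]))
}
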