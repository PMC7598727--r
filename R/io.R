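#' @title Trajectory tables
#' @description
#' A trajectory is a plain tibble with one row per bead and columns
#' `frame` (1-based index), `time` (simulation time, in the model's
#' intrinsic time unit tau), `peptide`, `residue`, `role` (one of
#' `"N"`, `"CA"`, `"C"`, `"SC"`), `x`, `y`, `z` (nm) and `box_x`,
#' `box_y`, `box_z` (periodic box edge lengths, nm). A single frame is
#' the same table filtered to one `frame` value. All package functions
#' consume and produce this shape, so analyses chain with the pipe.
#' Coordinates may lie outside the box; wrapping is handled by the
#' clustering functions via the minimum-image convention.
#' @name trajectory-table
NULL

frame_cols <- c("frame", "time", "peptide", "residue", "role",
                "x", "y", "z", "box_x", "box_y", "box_z")

check_frame_tbl <- function(df, single_frame = FALSE) {
  missing <- setdiff(frame_cols, names(df))
  if (length(missing) > 0) {
    stop("not a trajectory table; missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (single_frame && length(unique(df$frame)) != 1) {
    stop("expected a single frame; got ", length(unique(df$frame)),
         " (filter on `frame` first)", call. = FALSE)
  }
  invisible(df)
}

frame_box <- function(frame) {
  c(frame$box_x[1], frame$box_y[1], frame$box_z[1])
}

# Repair per-bead wrapping: place every bead at its minimum-image
# position relative to the peptide's first bead. Identity for intact
# peptides (extent < half the box edge), which is assumed throughout.
compact_peptides <- function(frame) {
  check_frame_tbl(frame)
  box <- frame_box(frame)
  dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(frame, .data$frame, .data$peptide),
    x = .data$x[1] + (.data$x - .data$x[1]) - box[1] * round((.data$x - .data$x[1]) / box[1]),
    y = .data$y[1] + (.data$y - .data$y[1]) - box[2] * round((.data$y - .data$y[1]) / box[2]),
    z = .data$z[1] + (.data$z - .data$z[1]) - box[3] * round((.data$z - .data$z[1]) / box[3])
  ))
}

assemble_trajectory <- function(coord_frames, times, boxes, topology) {
  bead_tbl <- topology_bead_table(topology)
  n_expected <- nrow(bead_tbl)
  if (any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  frames <- lapply(seq_along(coord_frames), function(i) {
    xyz <- coord_frames[[i]]
    if (nrow(xyz) != n_expected) {
      stop(sprintf(
        "topology error: frame %d has %d beads, expected %d (%d peptides x %d beads)",
        i, nrow(xyz), n_expected, topology$n_peptides, topology$beads_per_peptide
      ), call. = FALSE)
    }
    tibble::tibble(
      frame = as.integer(i),
      time = times[i],
      peptide = bead_tbl$peptide,
      residue = bead_tbl$residue,
      role = bead_tbl$role,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      box_x = boxes[[i]][1], box_y = boxes[[i]][2], box_z = boxes[[i]][3]
    )
  })
  dplyr::bind_rows(frames)
}

#' Read a coordinate trajectory and bind it to a peptide topology
#'
#' Reads XYZ, PDB or GRO coordinate files (one model/block per time
#' point) into the tidy trajectory table described in
#' [trajectory-table]. Internal coordinates are always nm: PDB
#' Angstroms are divided by 10 on input, GRO is nm natively, and the
#' XYZ unit is declared via `xyz_unit`.
#'
#' @param path Path to the coordinate file.
#' @param topology A [peptide_topology()] describing the beads; the bead
#'   count of every frame must match it.
#' @param format `"auto"` (by file extension), `"xyz"`, `"pdb"` or `"gro"`.
#' @param xyz_unit Length unit of XYZ files: `"nm"` (default) or
#'   `"angstrom"`.
#' @param default_box Box edge lengths (nm) used when the file carries no
#'   box record; `NULL` (default) makes a missing box an error.
#' @return A trajectory tibble (see [trajectory-table]).
#' @export
read_trajectory <- function(path, topology,
                            format = c("auto", "xyz", "pdb", "gro"),
                            xyz_unit = c("nm", "angstrom"),
                            default_box = NULL) {
  format <- match.arg(format)
  xyz_unit <- match.arg(xyz_unit)
  if (!file.exists(path)) stop("trajectory file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xyz = "xyz", pdb = "pdb", gro = "gro",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass `format`", call. = FALSE))
  }
  parsed <- switch(format,
    xyz = parse_xyz(path, xyz_unit),
    pdb = parse_pdb(path),
    gro = parse_gro(path)
  )
  boxes <- parsed$boxes
  for (i in seq_along(boxes)) {
    if (any(is.na(boxes[[i]]))) {
      if (is.null(default_box)) {
        stop("frame ", i, " carries no box record and no `default_box` was given",
             call. = FALSE)
      }
      boxes[[i]] <- rep(default_box, length.out = 3)
    }
    if (any(boxes[[i]] <= 0)) stop("frame ", i, " has non-positive box edge", call. = FALSE)
  }
  times <- parsed$times
  if (all(is.na(times))) times <- seq_along(parsed$coords) - 1
  if (any(is.na(times))) stop("some frames carry a time record and some do not", call. = FALSE)
  assemble_trajectory(parsed$coords, times, boxes, topology)
}

parse_xyz <- function(path, xyz_unit) {
  lines <- readLines(path)
  scale <- if (xyz_unit == "angstrom") 0.1 else 1
  coords <- list(); times <- numeric(); boxes <- list()
  i <- 1; fr <- 0
  while (i <= length(lines)) {
    if (!grepl("^\\s*$", lines[i])) {
      n <- suppressWarnings(as.integer(trimws(lines[i])))
      if (is.na(n)) stop("format error at line ", i, ": expected atom count", call. = FALSE)
      fr <- fr + 1
      comment <- if (i + 1 <= length(lines)) lines[i + 1] else ""
      tm <- regmatches(comment, regexec("time=([-0-9.eE+]+)", comment))[[1]]
      bx <- regmatches(comment, regexec("box=([-0-9.eE+]+),([-0-9.eE+]+),([-0-9.eE+]+)", comment))[[1]]
      times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else NA_real_)
      boxes[[fr]] <- if (length(bx) == 4) as.numeric(bx[2:4]) * scale else rep(NA_real_, 3)
      body <- lines[(i + 2):(i + 1 + n)]
      if (length(body) < n || anyNA(body)) {
        stop("format error: frame ", fr, " truncated after line ", i, call. = FALSE)
      }
      toks <- strsplit(trimws(body), "\\s+")
      bad <- which(vapply(toks, length, 1L) < 4)
      if (length(bad) > 0) {
        stop("format error at line ", i + 1 + bad[1], ": expected 'name x y z'", call. = FALSE)
      }
      xyz <- suppressWarnings(t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3))))
      if (anyNA(xyz)) stop("format error: non-numeric coordinate in frame ", fr, call. = FALSE)
      coords[[fr]] <- xyz * scale
      i <- i + 2 + n
    } else {
      i <- i + 1
    }
  }
  list(coords = coords, times = times, boxes = boxes)
}

parse_gro <- function(path) {
  lines <- readLines(path)
  coords <- list(); times <- numeric(); boxes <- list()
  i <- 1; fr <- 0
  while (i <= length(lines)) {
    if (grepl("^\\s*$", lines[i])) { i <- i + 1; next }
    fr <- fr + 1
    title <- lines[i]
    tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else NA_real_)
    n <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(n)) stop("format error at line ", i + 1, ": expected atom count", call. = FALSE)
    body <- lines[(i + 2):(i + 1 + n)]
    xyz <- cbind(
      as.numeric(substr(body, 21, 28)),
      as.numeric(substr(body, 29, 36)),
      as.numeric(substr(body, 37, 44))
    )
    if (anyNA(xyz)) {
      stop("format error: malformed coordinate record in frame ", fr, call. = FALSE)
    }
    coords[[fr]] <- xyz
    boxline <- as.numeric(strsplit(trimws(lines[i + 2 + n]), "\\s+")[[1]])
    boxes[[fr]] <- if (length(boxline) >= 3) boxline[1:3] else rep(NA_real_, 3)
    i <- i + 3 + n
  }
  list(coords = coords, times = times, boxes = boxes)
}

parse_pdb <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB requires the bio3d package", call. = FALSE)
  }
  lines <- readLines(path)
  cryst <- grep("^CRYST1", lines, value = TRUE)
  box <- if (length(cryst) >= 1) {
    as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                 substr(cryst[1], 25, 33))) * 0.1
  } else {
    rep(NA_real_, 3)
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  coords <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE) * 0.1
  })
  list(coords = coords, times = rep(NA_real_, length(coords)),
       boxes = rep(list(box), length(coords)))
}

#' Write a trajectory table to a coordinate file
#'
#' Inverse of [read_trajectory()]. XYZ carries `time=` and `box=` on the
#' comment line (nm); PDB writes one `MODEL` per frame with a `CRYST1`
#' box record (Angstroms); GRO writes one block per frame with the box
#' on the trailing line (nm).
#'
#' @param traj A trajectory tibble (see [trajectory-table]).
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"xyz"`, `"pdb"` or `"gro"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "xyz", "pdb", "gro")) {
  check_frame_tbl(traj)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xyz = "xyz", pdb = "pdb", gro = "gro",
                     stop("cannot infer format from extension '.", ext, "'", call. = FALSE))
  }
  frames <- split(traj, traj$frame)
  con <- file(path, "w")
  on.exit(close(con))
  for (fi in seq_along(frames)) {
    fr <- frames[[fi]]
    box <- frame_box(fr)
    if (format == "xyz") {
      writeLines(as.character(nrow(fr)), con)
      writeLines(sprintf("time=%.10g box=%.10g,%.10g,%.10g",
                         fr$time[1], box[1], box[2], box[3]), con)
      writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", fr$role, fr$x, fr$y, fr$z), con)
    } else if (format == "gro") {
      writeLines(sprintf("fibriltwist frame, t= %.10g", fr$time[1]), con)
      writeLines(sprintf("%5d", nrow(fr)), con)
      resglob <- (fr$peptide - 1) * max(fr$residue) + fr$residue
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         resglob %% 100000, "PEP", fr$role,
                         seq_len(nrow(fr)) %% 100000, fr$x, fr$y, fr$z), con)
      writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
    } else {
      if (fi == 1) {
        writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                           box[1] * 10, box[2] * 10, box[3] * 10, 90, 90, 90), con)
      }
      writeLines(sprintf("MODEL     %4d", fi), con)
      resglob <- (fr$peptide - 1) * max(fr$residue) + fr$residue
      writeLines(sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                         seq_len(nrow(fr)) %% 100000, fr$role, "UNK",
                         resglob %% 10000, fr$x * 10, fr$y * 10, fr$z * 10, 1, 0), con)
      writeLines("ENDMDL", con)
    }
  }
  if (format == "pdb") writeLines("END", con)
  invisible(path)
}

#' Per-peptide mass centers of a frame
#'
#' Equal-mass centroid of either all beads of each peptide or only the
#' side-chain bead of the designated residue (the tyrosine representation
#' used for fibril-axis fitting). Per-bead wrapping is repaired first so
#' the centroid of a peptide straddling a box face is meaningful.
#'
#' @param frame A single-frame trajectory tibble.
#' @param selection `"all_beads"` or `"side_chain"`.
#' @param side_chain_residue Residue index whose side-chain bead is used
#'   for `selection = "side_chain"`; default is the highest residue index
#'   that carries an SC bead.
#' @return A tibble with columns `peptide`, `x`, `y`, `z` (nm).
#' @export
peptide_mass_centers <- function(frame,
                                 selection = c("all_beads", "side_chain"),
                                 side_chain_residue = NULL) {
  selection <- match.arg(selection)
  check_frame_tbl(frame, single_frame = TRUE)
  frame <- compact_peptides(frame)
  if (selection == "side_chain") {
    sc <- dplyr::filter(frame, .data$role == "SC")
    if (is.null(side_chain_residue)) {
      if (nrow(sc) == 0) {
        stop("configuration error: no side-chain beads in this topology", call. = FALSE)
      }
      side_chain_residue <- max(sc$residue)
    }
    frame <- dplyr::filter(sc, .data$residue == side_chain_residue)
    if (nrow(frame) == 0) {
      stop("configuration error: designated residue ", side_chain_residue,
           " has no side-chain bead (glycine?)", call. = FALSE)
    }
  }
  dplyr::summarise(
    dplyr::group_by(frame, .data$peptide),
    x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
    .groups = "drop"
  )
}
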