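#' Read a TPS landmark file
#'
#' Parses the TPS dialect written by tpsDig-family digitizers: records start
#' with `LM=<n>` (case-insensitive), followed by `n` coordinate lines of two
#' whitespace-separated reals, and optional `ID=`, `IMAGE=` and `SCALE=`
#' lines. `IMAGE=` lines are ignored; `SCALE=` multiplies coordinates on
#' read. Alternatively, `format = "matrix"` reads a plain aligned-coordinate
#' matrix (one specimen per row, columns `x1 y1 x2 y2 ...`), the layout used
#' by tpsRelw when exporting aligned specimens.
#'
#' @param path path to the file, or a character vector of lines.
#' @param roles optional per-point role flags (`"fixed"`/`"semi"`); default
#'   [default_roles()] (beak scheme for 21 points, all fixed otherwise).
#' @param flip_y flip the sign of y on read, for digitizations made in image
#'   coordinates (origin top-left). Default `FALSE`.
#' @param format `"tps"` (default) or `"matrix"`.
#' @param species optional named character vector mapping specimen ids to
#'   species labels.
#' @return a landmark tibble with columns `specimen_id`, `species`, `point`,
#'   `x`, `y`, `role` (records and points kept in file order).
#' @export
read_tps <- function(path, roles = NULL, flip_y = FALSE,
                     format = c("tps", "matrix"), species = NULL) {
  format <- match.arg(format)
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  if (format == "matrix") {
    return(read_landmark_matrix(lines, roles = roles, flip_y = flip_y, species = species))
  }
  lines <- trimws(lines)
  is_lm <- grepl("^lm\\s*=", lines, ignore.case = TRUE)
  if (!any(is_lm)) abort("no LM= record headers found; not a TPS file?")
  starts <- which(is_lm)
  ends <- c(starts[-1L] - 1L, length(lines))
  seen <- character(0)
  recs <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    n_declared <- suppressWarnings(as.integer(sub("^lm\\s*=\\s*", "", block[[1L]], ignore.case = TRUE)))
    if (is.na(n_declared)) abort(sprintf("record %d: unparseable LM= count", r))
    body <- block[-1L]
    body <- body[nzchar(body)]
    is_key <- grepl("^[A-Za-z]+\\s*=", body)
    coord_lines <- body[!is_key]
    keys <- body[is_key]
    id <- sub("^id\\s*=\\s*", "", keys[grepl("^id\\s*=", keys, ignore.case = TRUE)][1L],
              ignore.case = TRUE)
    scale_txt <- sub("^scale\\s*=\\s*", "", keys[grepl("^scale\\s*=", keys, ignore.case = TRUE)][1L],
                     ignore.case = TRUE)
    if (length(coord_lines) != n_declared) {
      abort(sprintf("record %d (%s): LM=%d declared but %d coordinate lines found",
                    r, if (is.na(id)) "no ID" else id, n_declared, length(coord_lines)))
    }
    xy <- t(vapply(seq_along(coord_lines), function(i) {
      parts <- strsplit(coord_lines[[i]], "\\s+")[[1L]]
      v <- suppressWarnings(as.numeric(parts))
      if (length(v) != 2L || anyNA(v)) {
        abort(sprintf("record %d, coordinate line %d: not two numbers ('%s')",
                      r, i, coord_lines[[i]]))
      }
      v
    }, numeric(2L)))
    if (!is.na(scale_txt)) {
      sc <- suppressWarnings(as.numeric(scale_txt))
      if (is.na(sc) || sc <= 0) abort(sprintf("record %d: bad SCALE= value", r))
      xy <- xy * sc
    }
    if (flip_y) xy[, 2L] <- -xy[, 2L]
    if (is.na(id)) id <- sprintf("spec_%03d", r)
    if (id %in% seen) warn(sprintf("duplicate specimen id '%s'; keeping both records", id))
    seen <- c(seen, id)
    role_r <- if (is.null(roles)) default_roles(n_declared) else roles
    sp <- if (!is.null(species) && id %in% names(species)) unname(species[[id]]) else NA_character_
    recs[[r]] <- tibble::tibble(
      specimen_id = id, species = sp, point = seq_len(n_declared),
      x = xy[, 1L], y = xy[, 2L], role = role_r
    )
  }
  out <- dplyr::bind_rows(recs)
  # duplicate ids would collapse in downstream arrays; disambiguate row groups
  if (anyDuplicated(seen) > 0L) {
    dup_ord <- stats::ave(seq_along(seen), seen, FUN = seq_along)
    new_ids <- ifelse(dup_ord > 1L, paste0(seen, "_dup", dup_ord), seen)
    out$specimen_id <- rep(new_ids, each = nrow(out) / length(seen))
  }
  out
}

#' @keywords internal
read_landmark_matrix <- function(lines, roles = NULL, flip_y = FALSE, species = NULL) {
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) suppressWarnings(as.numeric(strsplit(trimws(l), "[,[:space:]]+")[[1L]])))
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L || widths[[1L]] %% 2L != 0L) {
    abort("matrix dialect: every row must have the same even number of values")
  }
  if (any(vapply(rows, anyNA, logical(1L)))) abort("matrix dialect: non-numeric cell")
  k <- widths[[1L]] %/% 2L
  role_r <- if (is.null(roles)) default_roles(k) else roles
  recs <- lapply(seq_along(rows), function(r) {
    v <- rows[[r]]
    id <- sprintf("spec_%03d", r)
    tibble::tibble(
      specimen_id = id,
      species = if (!is.null(species) && id %in% names(species)) unname(species[[id]]) else NA_character_,
      point = seq_len(k),
      x = v[seq(1L, 2L * k, by = 2L)],
      y = (if (flip_y) -1 else 1) * v[seq(2L, 2L * k, by = 2L)],
      role = role_r
    )
  })
  dplyr::bind_rows(recs)
}

#' Write a TPS landmark file
#'
#' Emits `LM=` / coordinate / `ID=` blocks readable by [read_tps()], with
#' full-precision coordinates.
#'
#' @param landmarks landmark tibble (see [read_tps()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(landmarks, path) {
  if (nrow(landmarks) == 0L) abort("no configurations to write")
  validate_landmarks(landmarks)
  ids <- unique(landmarks$specimen_id)
  out <- unlist(lapply(ids, function(id) {
    d <- landmarks[landmarks$specimen_id == id, ]
    d <- d[order(d$point), ]
    c(sprintf("LM=%d", nrow(d)),
      sprintf("%.17g %.17g", d$x, d$y),
      sprintf("ID=%s", id))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read a specimen measurement table
#'
#' Reads a delimited table of per-specimen linear measurements. The file must
#' carry columns for the six traits (`body_weight`, `body_length`,
#' `wing_length`, `tail_length`, `tarsus_length`, `culmen_length`) and
#' `species`; `specimen_id` and `altitude` are optional. Column names can be
#' remapped through `col_map` when the source file uses different headers.
#' Unparseable numeric cells (for example `"n/a"`) become `NA`, flagged in the
#' returned attribute `n_flagged_missing`, never silently zero.
#'
#' @param path path to a CSV/TSV file.
#' @param col_map optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(body_weight = "Weight(g)")`.
#' @return tibble with one row per specimen.
#' @export
read_measurements <- function(path, col_map = NULL) {
  raw <- readr::read_delim(path, delim = guess_delim(path), col_types = readr::cols(.default = "c"),
                           show_col_types = FALSE, progress = FALSE)
  canon <- c("specimen_id", "species", trait_names(), "altitude")
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (col_map[[nm]] %in% names(raw)) names(raw)[names(raw) == col_map[[nm]]] <- nm
    }
  }
  mandatory <- c("species", trait_names())
  miss <- setdiff(mandatory, names(raw))
  if (length(miss) > 0L) {
    abort(paste0("measurement table lacks mandatory column(s): ", paste(miss, collapse = ", ")))
  }
  out <- raw[, intersect(canon, names(raw))]
  if (!"specimen_id" %in% names(out)) out$specimen_id <- sprintf("spec_%03d", seq_len(nrow(out)))
  if (!"altitude" %in% names(out)) out$altitude <- NA_character_
  n_flagged <- 0L
  for (v in c(trait_names(), "altitude")) {
    parsed <- suppressWarnings(as.numeric(out[[v]]))
    n_flagged <- n_flagged + sum(is.na(parsed) & !is.na(out[[v]]) & nzchar(trimws(out[[v]])))
    out[[v]] <- parsed
  }
  if (any(!is.na(out$species) & !nzchar(out$species))) abort("empty species label")
  bad <- vapply(trait_names(), function(v) any(out[[v]] <= 0, na.rm = TRUE), logical(1L))
  if (any(bad)) {
    abort(paste0("nonpositive measurement in column(s): ",
                 paste(trait_names()[bad], collapse = ", ")))
  }
  out <- tibble::as_tibble(out[, canon])
  attr(out, "n_flagged_missing") <- n_flagged
  out
}

#' @keywords internal
guess_delim <- function(path) {
  l <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", l)) "\t" else ","
}

#' Read a rooted phylogeny from Newick text or file
#'
#' Thin wrapper around [ape::read.tree()] adding the checks the comparative
#' stages rely on: unique tip labels and a branch length on every edge
#' (absent lengths default to `default_length`, with a message).
#'
#' @param path_or_text path to a `.tre`/`.nwk` file, or a Newick string.
#' @param default_length branch length assigned when the source has none.
#' @return an object of class `phylo`.
#' @export
read_newick <- function(path_or_text, default_length = 1) {
  txt <- path_or_text
  if (length(txt) == 1L && !grepl(";", txt) && file.exists(txt)) {
    tree <- ape::read.tree(txt)
  } else {
    tree <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  }
  if (is.null(tree)) abort("could not parse Newick input (unbalanced parentheses?)")
  if (anyDuplicated(tree$tip.label) > 0L) {
    abort(paste0("duplicate tip labels: ",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", ")))
  }
  if (is.null(tree$edge.length)) {
    inform(sprintf("tree has no branch lengths; defaulting every edge to %g", default_length))
    tree$edge.length <- rep(default_length, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    inform(sprintf("missing branch lengths defaulted to %g", default_length))
    tree$edge.length[is.na(tree$edge.length)] <- default_length
  }
  if (any(tree$edge.length < 0)) abort("negative branch length")
  tree
}

#' Read species range and pairwise overlap tables
#'
#' @param ranges_path CSV with columns `species`, `area`, `alt_min`,
#'   `alt_max` (areas in km^2, altitudes in m).
#' @param overlaps_path CSV in long format with columns `species_a`,
#'   `species_b`, `overlap_area`.
#' @return list with tibbles `ranges` and `overlaps`.
#' @export
read_ranges <- function(ranges_path, overlaps_path = NULL) {
  ranges <- readr::read_csv(ranges_path, show_col_types = FALSE, progress = FALSE)
  need <- c("species", "area", "alt_min", "alt_max")
  miss <- setdiff(need, names(ranges))
  if (length(miss) > 0L) abort(paste0("range table lacks column(s): ", paste(miss, collapse = ", ")))
  if (any(ranges$area <= 0)) abort("range areas must be positive")
  if (any(ranges$alt_min > ranges$alt_max)) abort("alt_min must not exceed alt_max")
  overlaps <- NULL
  if (!is.null(overlaps_path)) {
    overlaps <- readr::read_csv(overlaps_path, show_col_types = FALSE, progress = FALSE)
    need_o <- c("species_a", "species_b", "overlap_area")
    miss_o <- setdiff(need_o, names(overlaps))
    if (length(miss_o) > 0L) abort(paste0("overlap table lacks column(s): ", paste(miss_o, collapse = ", ")))
  }
  list(ranges = tibble::as_tibble(ranges), overlaps = overlaps)
}

#' Write a synthetic study to disk in the pipeline's exchange formats
#'
#' Emits the same TPS/CSV/Newick files the readers consume: `landmarks.tps`,
#' `measurements.csv`, `tree.nwk`, `ranges.csv`, `overlaps.csv`.
#'
#' @param study a `parid_study` from [generate_study()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "parid_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    landmarks = file.path(dir, "landmarks.tps"),
    measurements = file.path(dir, "measurements.csv"),
    tree = file.path(dir, "tree.nwk"),
    ranges = file.path(dir, "ranges.csv"),
    overlaps = file.path(dir, "overlaps.csv")
  )
  write_tps(study$landmarks, paths[["landmarks"]])
  readr::write_csv(study$measurements, paths[["measurements"]])
  ape::write.tree(study$tree, paths[["tree"]], digits = 15)
  readr::write_csv(study$ranges, paths[["ranges"]])
  readr::write_csv(study$overlaps, paths[["overlaps"]])
  invisible(paths)
}

#' Read a study back from the exchange files written by [write_study()]
#'
#' Species labels for landmark configurations are recovered by joining the
#' measurement table on `specimen_id`.
#'
#' @param dir directory containing the exchange files.
#' @return a `parid_study` list (without a `truth` element).
#' @export
read_study <- function(dir) {
  meas <- read_measurements(file.path(dir, "measurements.csv"))
  sp <- setNames(meas$species, meas$specimen_id)
  lms <- read_tps(file.path(dir, "landmarks.tps"), species = sp)
  rg <- read_ranges(file.path(dir, "ranges.csv"), file.path(dir, "overlaps.csv"))
  structure(
    list(tree = read_newick(file.path(dir, "tree.nwk")),
         landmarks = lms, measurements = meas,
         ranges = rg$ranges, overlaps = rg$overlaps, truth = NULL, config = NULL),
    class = "parid_study"
  )
}

#' Load the deposited Paridae study data, if present
#'
#' The original study deposited its raw inputs as supplementary files: a
#' measurement table for 376 museum specimens (CSV), aligned landmark
#' coordinates for 306 beak profiles (plain-text matrix, one specimen per
#' row), and a 14-taxon Newick tree. When copies of those files are placed in
#' a directory as `body_measurements.csv`, `aligned_coordinates.txt` and
#' `phylogeny.tre`, this loader ingests them through the package's readers.
#' The files are not redistributed with the package.
#'
#' @param dir directory holding the deposited files.
#' @param col_map passed to [read_measurements()]; the deposited CSV's exact
#'   header layout is configurable.
#' @return list with `measurements`, `landmarks` (aligned coordinates, matrix
#'   dialect) and `tree`.
#' @export
read_deposited_study <- function(dir, col_map = NULL) {
  paths <- file.path(dir, c("body_measurements.csv", "aligned_coordinates.txt", "phylogeny.tre"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    abort(paste0(
      "deposited study files not found: ", paste(basename(missing), collapse = ", "),
      ". Obtain the study's supplementary data files and place them in '", dir, "'."
    ))
  }
  list(
    measurements = read_measurements(paths[[1L]], col_map = col_map),
    landmarks = read_tps(paths[[2L]], format = "matrix"),
    tree = read_newick(paths[[3L]])
  )
}
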