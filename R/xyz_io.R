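#' Read structures from an XYZ or extended-XYZ file
#'
#' Parses one or more concatenated frames. Extended-XYZ comment lines of
#' the form `key=value ...` are stored as frame metadata. Pivot and
#' hydrogen-bond annotations are read from a JSON sidecar
#' (`<path>.json`) when present, turning each frame into a full
#' [molecular_frame()]; without a sidecar, bare frames (labels, elements,
#' coordinates) are returned.
#'
#' @param path File path.
#' @param sidecar Optional explicit sidecar path (default `<path>.json` if
#'   it exists).
#' @return List of [molecular_frame()]s (possibly empty).
#' @export
read_structures <- function(path, sidecar = NULL) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1) {
      stop("read_structures(): expected an atom count at line ", i,
           " of ", path, ", got '", lines[i], "'")
    }
    if (i + 1L + nat > length(lines)) {
      stop("read_structures(): truncated frame at line ", i, " of ", path,
           " (", nat, " atoms declared, file ends at line ", length(lines), ")")
    }
    comment <- lines[i + 1L]
    rows <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(rows), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad)) {
      stop("read_structures(): malformed atom record at line ",
           i + 1L + bad[1], " of ", path)
    }
    elements <- vapply(parts, `[`, character(1), 1)
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(coords))) {
      stop("read_structures(): non-numeric coordinates near line ", i + 2L,
           " of ", path)
    }
    labels <- vapply(parts, function(p) {
      if (length(p) >= 5) p[5] else p[1]
    }, character(1))
    frames[[length(frames) + 1]] <- list(labels = labels, elements = elements,
                                         coords = coords, comment = comment)
    i <- i + 2L + nat
  }
  if (is.null(sidecar)) {
    cand <- paste0(path, ".json")
    if (file.exists(cand)) sidecar <- cand
  }
  if (!is.null(sidecar)) {
    ann <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    frames <- lapply(frames, function(fr) {
      hb <- lapply(seq_len(nrow(ann$hbonds)), function(k) {
        hbond_spec(ann$hbonds$donor[k], ann$hbonds$hydrogen[k],
                   ann$hbonds$acceptor[k], ann$hbonds$label[k],
                   ann$hbonds$eq_length[k])
      })
      eqr <- ann$equilibrium_reference
      if (!is.null(eqr) && !is.matrix(eqr)) {
        eqr <- matrix(unlist(eqr), ncol = 3, byrow = TRUE)
      }
      molecular_frame(fr$labels, fr$elements, fr$coords,
                      pivot_indices = ann$pivot_indices, hbonds = hb,
                      equilibrium_reference = eqr)
    })
  }
  frames
}

#' Write structures to an extended-XYZ file
#'
#' Writes each frame with a `Properties=species:S:1:pos:R:3:label:S:1`
#' comment line; [molecular_frame()] annotations (pivots, hydrogen bonds,
#' equilibrium reference) go to a JSON sidecar at `<path>.json` so a
#' round trip preserves them.
#'
#' @param frames A [molecular_frame()] or list of them (bare frames with
#'   `labels`/`elements`/`coords` are also accepted).
#' @param path Output file path.
#' @param digits Coordinate precision (decimal digits).
#' @return `path`, invisibly.
#' @export
write_structures <- function(frames, path, digits = 10) {
  if (inherits(frames, "molecular_frame") ||
      (is.list(frames) && !is.null(frames$coords))) {
    frames <- list(frames)
  }
  out <- character(0)
  for (fr in frames) {
    n <- nrow(fr$coords)
    fmt <- paste0("%-3s % .", digits, "f % .", digits, "f % .", digits, "f %s")
    rows <- vapply(seq_len(n), function(k) {
      sprintf(fmt, fr$elements[k], fr$coords[k, 1], fr$coords[k, 2],
              fr$coords[k, 3], fr$labels[k])
    }, character(1))
    out <- c(out, as.character(n),
             'Properties=species:S:1:pos:R:3:label:S:1', rows)
  }
  writeLines(out, path)
  fr1 <- frames[[1]]
  if (inherits(fr1, "molecular_frame")) {
    ann <- list(
      pivot_indices = fr1$pivot_indices,
      hbonds = data.frame(
        donor = vapply(fr1$hbonds, function(h) h$donor, integer(1)),
        hydrogen = vapply(fr1$hbonds, function(h) h$hydrogen, integer(1)),
        acceptor = vapply(fr1$hbonds, function(h) h$acceptor, integer(1)),
        label = vapply(fr1$hbonds, function(h) h$label, character(1)),
        eq_length = vapply(fr1$hbonds, function(h) h$eq_length, numeric(1))
      ),
      equilibrium_reference = fr1$equilibrium_reference
    )
    jsonlite::write_json(ann, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
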