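# Canonical on-disk form of a CBBA is a JSON document:
#   {"frame": ["a","b"],
#    "masses": [{"subset": ["a"], "re": 0.6, "im": 0.1}, ...]}
# On input each mass entry may instead use {"magnitude", "phase"} or
# {"magnitude", "phase_tan"} (exactly one form per entry); output is always
# Cartesian so that write -> read round trips losslessly.

#' Read a CBBA from canonical JSON
#'
#' @param path Path to a JSON file (or a connection) with fields `frame`
#'   (array of element labels) and `masses` (array of entries; each entry
#'   has `subset` plus exactly one of the value forms `re`/`im`,
#'   `magnitude`/`phase`, or `magnitude`/`phase_tan`).
#' @param tol_norm Normalization tolerance passed to [cbba()]; use
#'   `cbba_tol(paper_rounded = TRUE)` for files transcribed from rounded
#'   polar tables.
#' @return A validated `cbba` object.
#' @export
read_cbba <- function(path, tol_norm = 1e-9) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$frame) || is.null(doc$masses)) {
    stop("CBBA JSON must declare both 'frame' and 'masses'", call. = FALSE)
  }
  frame <- fod(unlist(doc$frame))
  subsets <- vector("list", length(doc$masses))
  mass <- complex(length(doc$masses))
  for (i in seq_along(doc$masses)) {
    e <- doc$masses[[i]]
    if (is.null(e$subset)) {
      stop(sprintf("mass entry %d lacks a 'subset'", i), call. = FALSE)
    }
    subsets[[i]] <- as.character(unlist(e$subset))
    mass[i] <- parse_mass_entry(e, i)
  }
  cbba(frame, subsets, mass, tol_norm = tol_norm)
}

parse_mass_entry <- function(e, i) {
  cart <- !is.null(e[["re"]]) || !is.null(e[["im"]])
  polar <- !is.null(e[["magnitude"]])
  if (cart && polar) {
    stop(sprintf(
      "mass entry %d mixes Cartesian and polar forms; use exactly one", i),
      call. = FALSE)
  }
  if (cart) {
    return(complex(
      real = if (is.null(e[["re"]])) 0 else as.numeric(e[["re"]]),
      imaginary = if (is.null(e[["im"]])) 0 else as.numeric(e[["im"]])))
  }
  if (polar) {
    has_phase <- !is.null(e[["phase"]])
    has_tan <- !is.null(e[["phase_tan"]])
    if (has_phase && has_tan) {
      stop(sprintf(
        "mass entry %d gives both 'phase' and 'phase_tan'", i), call. = FALSE)
    }
    m <- as.numeric(e[["magnitude"]])
    if (has_tan) return(from_polar_tan(m, as.numeric(e[["phase_tan"]])))
    return(from_polar(m, if (has_phase) as.numeric(e[["phase"]]) else 0))
  }
  stop(sprintf(
    "mass entry %d has no value: give re/im, magnitude/phase, or magnitude/phase_tan",
    i), call. = FALSE)
}

#' Write a CBBA to canonical JSON
#'
#' Always writes the Cartesian form, so [read_cbba()] reproduces the CBBA
#' exactly.
#'
#' @param M A `cbba` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cbba <- function(M, path) {
  stopifnot(inherits(M, "cbba"))
  doc <- list(
    frame = M$frame$elements,
    masses = lapply(seq_along(M$keys), function(i) list(
      subset = key_members(M$frame, M$keys[i]),
      re = Re(M$mass[i]),
      im = Im(M$mass[i])))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read attributed evidence from CSV
#'
#' Reads a flat CSV with one row per (entity, attribute, subset) mass.
#' Columns: `entity`, `attribute`, `subset` (member labels joined by `|`),
#' and either `magnitude` + `phase_tan` or `re` + `im`. The frame must be
#' declared, either by a leading comment line `# frame: y|n` in the file or
#' through the `frame` argument (which takes precedence); it is never
#' inferred from the subsets present.
#'
#' @param path CSV path.
#' @param frame Optional [fod()] declaring the frame.
#' @param tol_norm Normalization tolerance for the per-attribute CBBAs.
#' @return A named list of [attributed_evidence()] objects, one per entity,
#'   in order of first appearance. All entities must cover the same
#'   attribute set.
#' @export
read_attributed <- function(path, frame = NULL, tol_norm = 1e-9) {
  if (is.null(frame)) {
    first <- readLines(path, n = 1L)
    m <- regmatches(first, regexec("^#\\s*frame:\\s*(.+)$", first))[[1]]
    if (length(m) == 2L) {
      frame <- fod(trimws(strsplit(m[2], "|", fixed = TRUE)[[1]]))
    } else {
      stop("no frame declared: pass `frame` or start the file with '# frame: a|b'",
           call. = FALSE)
    }
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("entity", "attribute", "subset")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns entity, attribute, subset plus a value form",
         call. = FALSE)
  }
  cart <- all(c("re", "im") %in% names(df))
  polar <- all(c("magnitude", "phase_tan") %in% names(df))
  if (!cart && !polar) {
    stop("CSV must carry either re,im or magnitude,phase_tan columns",
         call. = FALSE)
  }
  mass <- if (cart) complex(real = df$re, imaginary = df$im)
          else from_polar_tan(df$magnitude, df$phase_tan)
  entities <- unique(df$entity)
  out <- lapply(entities, function(ent) {
    rows <- df$entity == ent
    attrs <- unique(df$attribute[rows])
    ev <- lapply(attrs, function(a) {
      sel <- rows & df$attribute == a
      subsets <- strsplit(df$subset[sel], "|", fixed = TRUE)
      cbba(frame, subsets, mass[sel], tol_norm = tol_norm)
    })
    names(ev) <- attrs
    attributed_evidence(ent, ev)
  })
  names(out) <- entities
  attr_sets <- lapply(out, function(e) sort(names(e$evidence)))
  if (length(unique(attr_sets)) > 1L) {
    stop("entities cover different attribute sets: ",
         paste(vapply(out, function(e)
           sprintf("%s{%s}", e$id, paste(names(e$evidence), collapse = ",")),
           character(1)), collapse = "; "),
         call. = FALSE)
  }
  out
}

#' Write a classification or distance report
#'
#' Writes a TSV with stable column order. For a `classification_result`
#' the columns are `sample`, `pattern`, `distance` (full precision),
#' `distance_4dp` (display rounding), `rank`, and `chosen`, one row per
#' pattern in ranking order.
#'
#' @param result A `classification_result` (or a data frame, written
#'   as-is).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  if (inherits(result, "classification_result")) {
    ord <- match(result$ranking, names(result$distances))
    df <- data.frame(
      sample = result$sample_id,
      pattern = names(result$distances)[ord],
      distance = unname(result$distances)[ord],
      distance_4dp = sprintf("%.4f", unname(result$distances)[ord]),
      rank = seq_along(ord),
      chosen = names(result$distances)[ord] == result$chosen)
  } else if (is.data.frame(result)) {
    df <- result
  } else {
    stop("unsupported report object", call. = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
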