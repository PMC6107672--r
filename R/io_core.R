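# Generic datacube I/O plus the plain-array exchange format: a single JSON
# document holding coordinates, axis and intensities at full double precision,
# so round-trips are exact and tests need no binary parser.

#' Write a dataset (imzML or plain-array JSON)
#'
#' Dispatches on the file extension: `.imzML` writes the open imaging-MS
#' standard (plus `.ibd`), `.json` writes the package's plain-array exchange
#' format. `read_msi(write_msi(d, p))` reproduces `d`'s pixels, axis and
#' intensities exactly for the JSON format and to float32 resolution for
#' imzML intensities.
#'
#' @param d an `msi_dataset`
#' @param path output file path ending in `.imzML` or `.json`
#' @param ... passed on to the format-specific writer
#' @return `path`, invisibly
#' @export
write_msi <- function(d, path, ...) {
  validate_msi_dataset(d)
  if (grepl("\\.imzML$", path, ignore.case = TRUE)) {
    write_imzml(d, path, ...)
  } else if (grepl("\\.json$", path)) {
    payload <- list(
      format = "msimarkers-msi/1",
      mode = d$mode,
      shared_axis = d$shared_axis,
      section_id = d$section_id,
      group = d$group,
      pixel_pitch = d$pixel_pitch,
      x = d$coords$x,
      y = d$coords$y,
      mz = d$mz,
      intensities = if (d$shared_axis) {
        apply(d$intensities, 1L, identity, simplify = FALSE)
      } else {
        d$intensities
      },
      metadata = d$metadata
    )
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE, null = "null")
  } else {
    stop("write_msi: unknown extension (use .imzML or .json): ", path)
  }
  invisible(path)
}

#' Read a dataset (imzML or plain-array JSON)
#'
#' @param path path to a `.imzML` or `.json` datacube
#' @param ... passed on to the format-specific reader
#' @return an `msi_dataset`
#' @export
read_msi <- function(path, ...) {
  if (!file.exists(path)) stop("read_msi: no such file: ", path)
  if (grepl("\\.imzML$", path, ignore.case = TRUE)) {
    return(read_imzml(path, ...))
  }
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "msimarkers-msi/1")) {
    stop("read_msi: not a msimarkers plain-array file (format field '",
         p$format %||% "<missing>", "'): ", path)
  }
  shared <- isTRUE(p$shared_axis)
  ints <- if (shared) {
    m <- if (is.matrix(p$intensities)) p$intensities
         else do.call(rbind, lapply(p$intensities, as.numeric))
    storage.mode(m) <- "double"
    m
  } else {
    if (is.matrix(p$intensities)) {
      lapply(seq_len(nrow(p$intensities)), function(i) as.numeric(p$intensities[i, ]))
    } else {
      lapply(p$intensities, as.numeric)
    }
  }
  msi_dataset(
    coords = data.frame(x = p$x, y = p$y),
    mz = if (shared) as.numeric(p$mz) else lapply(p$mz, as.numeric),
    intensities = ints,
    mode = p$mode,
    section_id = p$section_id,
    group = if (is.null(p$group)) NA_character_ else p$group,
    pixel_pitch = p$pixel_pitch,
    metadata = as.list(p$metadata)
  )
}

#' Write a batch of sections to one directory
#'
#' Writes each section with [write_msi()] and a `manifest.json` listing every
#' file with its section id and group.
#'
#' @param datasets list of `msi_dataset`
#' @param dir output directory (created if needed)
#' @param format `"json"` or `"imzML"`
#' @return path to the manifest, invisibly
#' @export
write_msi_batch <- function(datasets, dir, format = c("json", "imzML")) {
  format <- match.arg(format)
  if (length(datasets) == 0) stop("write_msi_batch: nothing to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(datasets, function(d) {
    f <- file.path(dir, paste0(d$section_id, ".", if (format == "json") "json" else "imzML"))
    write_msi(d, f)
    list(file = basename(f), section_id = d$section_id, group = d$group)
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a batch of sections written by [write_msi_batch()]
#' @param dir directory containing `manifest.json`
#' @return list of `msi_dataset`
#' @export
read_msi_batch <- function(dir) {
  manifest <- file.path(dir, "manifest.json")
  if (!file.exists(manifest)) stop("read_msi_batch: no manifest.json in ", dir)
  entries <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  lapply(entries, function(e) read_msi(file.path(dir, e$file)))
}

PEPTIDE_ID_COLUMNS <- c("protein_accession", "gene_name", "description",
                        "sequence", "experimental_neutral_mass", "score")

#' Read a bottom-up LC-MS/MS peptide identification table
#'
#' Expects a delimited text export (comma-separated, header row) with the six
#' columns `protein_accession, gene_name, description, sequence,
#' experimental_neutral_mass, score`. Rows whose sequence contains a letter
#' outside the 20 standard residues, or whose mass is not a positive number,
#' are returned in the `rejected` attribute with a reason — reported, never
#' silently dropped.
#'
#' @param path CSV path
#' @return data.frame of valid rows (class `peptide_id_table`), with attribute
#'   `rejected` (data.frame of rejected rows and reasons)
#' @export
read_peptide_ids <- function(path) {
  if (!file.exists(path)) stop("read_peptide_ids: no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(PEPTIDE_ID_COLUMNS, names(tab))
  if (length(missing) > 0) {
    stop("read_peptide_ids: schema error; expected columns {",
         paste(PEPTIDE_ID_COLUMNS, collapse = ", "), "} but missing {",
         paste(missing, collapse = ", "), "}")
  }
  tab <- tab[, PEPTIDE_ID_COLUMNS]
  if (nrow(tab) == 0) {
    warning("read_peptide_ids: empty table (header only): ", path)
    return(as_peptide_id_table(tab, tab[0, , drop = FALSE]))
  }
  tab$sequence <- toupper(trimws(tab$sequence))
  reason <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    bad <- setdiff(strsplit(tab$sequence[i], "")[[1]], names(RESIDUE_MASSES))
    if (nchar(tab$sequence[i]) == 0) {
      reason[i] <- "empty sequence"
    } else if (length(bad) > 0) {
      reason[i] <- paste0("invalid residue ", paste(bad, collapse = ""))
    } else if (!is.finite(tab$experimental_neutral_mass[i]) ||
               tab$experimental_neutral_mass[i] <= 0) {
      reason[i] <- "nonpositive mass"
    }
  }
  rejected <- cbind(tab[reason != "", , drop = FALSE],
                    reason = reason[reason != ""])
  if (nrow(rejected) > 0) {
    warning("read_peptide_ids: rejected ", nrow(rejected), " row(s): ",
            paste(unique(rejected$reason), collapse = "; "))
  }
  as_peptide_id_table(tab[reason == "", , drop = FALSE], rejected)
}

as_peptide_id_table <- function(tab, rejected = NULL) {
  rownames(tab) <- NULL
  structure(tab, rejected = rejected,
            class = c("peptide_id_table", "data.frame"))
}

#' Write a peptide identification table
#' @param tab a `peptide_id_table` or compatible data.frame
#' @param path CSV path
#' @export
write_peptide_ids <- function(tab, path) {
  utils::write.csv(as.data.frame(tab)[, PEPTIDE_ID_COLUMNS], path,
                   row.names = FALSE)
  invisible(path)
}
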