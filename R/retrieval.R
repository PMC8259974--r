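# Acquisition of structure and SIFTS files. All network use lives here,
# behind an injectable fetcher, so every other module is testable offline.

#' Default download endpoints
#'
#' Asymmetric units come from RCSB; assemblies and SIFTS per-entry XML from
#' PDBe. Each entry is an sprintf template taking the lower-case entry id
#' (and the assembly number where applicable). Endpoints are configuration,
#' not behavior: override them if the URLs drift.
#'
#' @return named list of URL templates.
#' @export
defaultEndpoints <- function() {
    list(
        mmCIF = "https://files.rcsb.org/download/%s.cif.gz",
        PDB = "https://files.rcsb.org/download/%s.pdb.gz",
        mmCIF_assembly = "https://www.ebi.ac.uk/pdbe/static/entry/download/%s-assembly-%d.cif.gz",
        PDB_assembly = "https://files.rcsb.org/download/%s.pdb%d.gz",
        SIFTS = "https://ftp.ebi.ac.uk/pub/databases/msd/sifts/split_xml/%s/%s.xml.gz"
    )
}

#' Default per-kind input and output directories
#'
#' @param base base directory (default: current directory).
#' @return named list of directories: inputs `mmCIF`, `mmCIF_assembly`,
#'   `PDB`, `PDB_assembly`, `SIFTS`; outputs `output_<kind>`.
#' @export
defaultPaths <- function(base = getwd()) {
    kinds <- c("mmCIF", "mmCIF_assembly", "PDB", "PDB_assembly")
    p <- c(stats::setNames(file.path(base, c(kinds, "SIFTS")),
                           c(kinds, "SIFTS")),
           stats::setNames(file.path(base, paste0("output_", kinds)),
                           paste0("output_", kinds)))
    as.list(p)
}

defaultFetcher <- function() {
    function(url, destfile) {
        status <- suppressWarnings(
            try(utils::download.file(url, destfile, quiet = TRUE,
                                     mode = "wb"), silent = TRUE))
        !inherits(status, "try-error") && identical(status, 0L) &&
            file.exists(destfile)
    }
}

#' Fetch a URL with bounded retry
#'
#' Makes at most `attempts` requests; the first success wins. Network-layer
#' errors are absorbed into the retry count and never escape: after all
#' attempts fail, the resource is marked `absent` (three bad responses in a
#' row are taken to mean the file does not exist) and the caller skips the
#' entry with a log record.
#'
#' @param url the URL.
#' @param destfile local destination path.
#' @param attempts maximum number of requests (default 3).
#' @param fetcher function(url, destfile) -> logical success; defaults to a
#'   wrapper over [utils::download.file()]. Tests inject mocks here.
#' @return a `FetchResult`: list with `url`, `outcome` ("ok"/"absent"),
#'   `path` (or NA), `attempts` used.
#' @export
fetchWithRetry <- function(url, destfile, attempts = 3L,
                           fetcher = defaultFetcher()) {
    attempts <- max(1L, as.integer(attempts))
    for (i in seq_len(attempts)) {
        ok <- tryCatch(isTRUE(fetcher(url, destfile)),
                       error = function(e) FALSE)
        if (ok)
            return(structure(list(url = url, outcome = "ok", path = destfile,
                                  attempts = i), class = "FetchResult"))
    }
    structure(list(url = url, outcome = "absent", path = NA_character_,
                   attempts = attempts), class = "FetchResult")
}

#' @export
print.FetchResult <- function(x, ...) {
    cat(sprintf("<FetchResult %s: %s after %d attempt(s)>\n",
                x$outcome, x$url, x$attempts))
    invisible(x)
}

#' Classify a user-supplied identifier
#'
#' Four characters with a leading digit is a PDB entry id; an identifier
#' containing "_" is a SwissProt-style ID (P53_HUMAN); anything else is
#' treated as a UniProt accession (P04637).
#'
#' @param ids character vector.
#' @return character vector: "pdb", "swissprot" or "accession".
#' @export
classifyIdentifier <- function(ids) {
    ifelse(grepl("^[0-9][A-Za-z0-9]{3}$", ids), "pdb",
           ifelse(grepl("_", ids, fixed = TRUE), "swissprot", "accession"))
}

#' Resolve mixed PDB/UniProt identifiers to PDB entry ids
#'
#' UniProt-form identifiers (accession or SwissProt ID) are expanded to all
#' PDB entries containing that sequence, per a pluggable mapping index;
#' PDB ids pass through. Duplicates are removed with input order preserved;
#' unresolvable identifiers are reported via a warning, never fatal.
#'
#' @param ids character vector of identifiers.
#' @param index data.frame with columns `accession`, `swissprot_id`,
#'   `pdb_id` (a flat-file UniProt-to-PDB mapping), or NULL when only PDB
#'   ids are expected.
#' @return character vector of lower-case 4-character PDB ids.
#' @examples
#' resolveIdentifiers(c("1d5t", "1bxw"))
#' @export
resolveIdentifiers <- function(ids, index = NULL) {
    if (!length(ids)) return(character())
    kind <- classifyIdentifier(ids)
    out <- list()
    bad <- character()
    for (i in seq_along(ids)) {
        id <- ids[i]
        if (kind[i] == "pdb") {
            out[[i]] <- tolower(id)
        } else if (is.null(index)) {
            bad <- c(bad, id)
        } else {
            hit <- if (kind[i] == "swissprot")
                index$pdb_id[index$swissprot_id == id]
            else index$pdb_id[index$accession == id]
            if (!length(hit)) bad <- c(bad, id) else out[[i]] <- tolower(hit)
        }
    }
    if (length(bad))
        warning("unresolvable identifier(s): ", paste(bad, collapse = ", "),
                call. = FALSE)
    unique(unlist(out) %||% character())
}

siftsUrl <- function(id, endpoints) {
    # split_xml layout keys on the middle two characters of the entry id
    sprintf(endpoints$SIFTS, substr(id, 2L, 3L), id)
}

#' Gather structure and SIFTS inputs for a set of entries
#'
#' Places each requested file under its per-kind input directory, reusing
#' files already present without refetching. SIFTS is always fetched
#' alongside the structures; an entry whose SIFTS file is absent is reported
#' so it can be passed through unrenumbered. Per-entry failures never abort
#' the batch.
#'
#' @param pdbIds character vector of 4-character entry ids.
#' @param kinds subset of `c("mmCIF", "PDB", "mmCIF_assembly",
#'   "PDB_assembly")`.
#' @param paths directory layout from [defaultPaths()].
#' @param endpoints URL templates from [defaultEndpoints()].
#' @param attempts retry bound per file.
#' @param fetcher injectable fetcher, see [fetchWithRetry()].
#' @param assembly assembly number for assembly kinds.
#' @return data.frame: `id`, `kind`, `outcome` ("ok"/"cached"/"absent"),
#'   `path`, `attempts`.
#' @export
gatherInputs <- function(pdbIds, kinds = "mmCIF", paths = defaultPaths(),
                         endpoints = defaultEndpoints(), attempts = 3L,
                         fetcher = defaultFetcher(), assembly = 1L) {
    kinds <- match.arg(kinds, c("mmCIF", "PDB", "mmCIF_assembly",
                                "PDB_assembly"), several.ok = TRUE)
    rows <- list()
    add <- function(id, kind, url, dir, fname) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        dest <- file.path(dir, fname)
        if (file.exists(dest)) {
            rows[[length(rows) + 1L]] <<- data.frame(
                id = id, kind = kind, outcome = "cached", path = dest,
                attempts = 0L, stringsAsFactors = FALSE)
            return()
        }
        fr <- fetchWithRetry(url, dest, attempts, fetcher)
        rows[[length(rows) + 1L]] <<- data.frame(
            id = id, kind = kind, outcome = fr$outcome,
            path = if (is.na(fr$path)) NA_character_ else fr$path,
            attempts = fr$attempts, stringsAsFactors = FALSE)
    }
    for (id in tolower(pdbIds)) {
        for (kind in kinds) {
            url <- switch(kind,
                mmCIF = sprintf(endpoints$mmCIF, id),
                PDB = sprintf(endpoints$PDB, id),
                mmCIF_assembly = sprintf(endpoints$mmCIF_assembly, id,
                                         as.integer(assembly)),
                PDB_assembly = sprintf(endpoints$PDB_assembly, id,
                                       as.integer(assembly)))
            fname <- switch(kind,
                mmCIF = paste0(id, ".cif.gz"),
                PDB = paste0(id, ".pdb.gz"),
                mmCIF_assembly = sprintf("%s-assembly-%d.cif.gz", id,
                                         as.integer(assembly)),
                PDB_assembly = sprintf("%s.pdb%d.gz", id,
                                       as.integer(assembly)))
            add(id, kind, url, paths[[kind]], fname)
        }
        add(id, "SIFTS", siftsUrl(id, endpoints), paths$SIFTS,
            paste0(id, ".xml.gz"))
    }
    do.call(rbind, rows)
}
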