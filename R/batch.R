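# Batch driver: fetch (or reuse) inputs, renumber, write outputs, report.

reportColumns <- c("PDB_id", "chain_PDB", "chain_auth", "UniProt",
                   "SwissProt", "uni_len", "chain_len", "renum",
                   "5k_or_50k", "SP")

emptyReport <- function() {
    r <- data.frame(PDB_id = character(), chain_PDB = character(),
                    chain_auth = character(), UniProt = character(),
                    SwissProt = character(), uni_len = integer(),
                    chain_len = integer(), renum = integer(),
                    offset_count = integer(), SP = character(),
                    stringsAsFactors = FALSE, check.names = FALSE)
    names(r)[9L] <- "5k_or_50k"
    r
}

planReport <- function(id, plan) {
    ch <- planChains(plan)
    if (!nrow(ch)) return(emptyReport())
    r <- data.frame(PDB_id = id, chain_PDB = ch$pdb_chain_id,
                    chain_auth = ch$auth_chain_id, UniProt = ch$accession,
                    SwissProt = ifelse(nzchar(ch$swissprot), ch$swissprot, "-"),
                    uni_len = ch$uni_len, chain_len = ch$chain_len,
                    renum = ch$renum, offset_count = ch$offset_count,
                    SP = ch$flag, stringsAsFactors = FALSE,
                    check.names = FALSE)
    names(r)[9L] <- "5k_or_50k"
    r
}

#' Renumber one entry from local input files
#'
#' Reads the entry's SIFTS file and structure file, computes the plan,
#' renumbers, and writes the `_renum`-tagged output. Entries whose SIFTS
#' file is missing, or whose chains carry no UniProt data, pass through
#' unrenumbered (no output is written) and are flagged in the result.
#'
#' @param id 4-character entry id (used for output naming).
#' @param structPath path to the mmCIF (`.cif[.gz]`) or legacy PDB
#'   (`.pdb[.gz]`) input.
#' @param siftsPath path to the entry's SIFTS XML, or NA when absent.
#' @param format `"mmcif"` or `"legacy"`.
#' @param outDir output directory (created if needed).
#' @param offsets an [OffsetConfig-class].
#' @param exceptions chaperone exception identifiers.
#' @param uniprotNames optional accession -> SwissProt ID lookup.
#' @param gzip write gzip-compressed output.
#' @param assembly assembly number or NA; assemblies are renumbered by
#'   matching their chains back to the asymmetric-unit plan (mmCIF only).
#' @return list with `id`, `status` ("ok", "no_sifts", "no_uniprot",
#'   "failed"), `outPath` (or NA), `report` (per-chain rows), `message`.
#' @export
renumberEntry <- function(id, structPath, siftsPath,
                          format = c("mmcif", "legacy"),
                          outDir = ".", offsets = offsetConfig(),
                          exceptions = chaperoneExceptions(),
                          uniprotNames = character(), gzip = TRUE,
                          assembly = NA) {
    format <- match.arg(format)
    if (is.na(siftsPath) || !file.exists(siftsPath))
        return(list(id = id, status = "no_sifts", outPath = NA_character_,
                    report = emptyReport(),
                    message = "no SIFTS file; entry not renumbered"))
    records <- parseSifts(siftsPath)
    chainMap <- resolveChainAccession(records, exceptions, uniprotNames)
    plan <- assignTargetNumbers(records, chainMap, offsets, format)
    if (nrow(planChains(plan)) == 0L)
        return(list(id = id, status = "no_uniprot", outPath = NA_character_,
                    report = emptyReport(),
                    message = "no UniProt data in SIFTS; entry not renumbered"))

    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    out <- file.path(outDir, renumFileName(id, format, gzip, assembly))
    if (format == "mmcif") {
        doc <- readMmcif(structPath)
        if (!is.na(assembly)) plan <- extendPlanToAssembly(plan, doc)
        writeMmcif(renumberMmcif(doc, plan, offsets), out, gzip)
    } else {
        lines <- readLegacy(structPath)
        out2 <- renumberLegacy(lines, plan, offsets)
        writeLegacy(as.character(out2), out, gzip)
    }
    list(id = id, status = "ok", outPath = out,
         report = planReport(id, plan), message = "")
}

#' Run the full renumbering batch
#'
#' For each entry and requested format: locate (or fetch) the structure and
#' SIFTS inputs, compute the plan, renumber, and write the `_renum` output,
#' the per-chain log report, and a TSV log file. Per-entry failures are
#' isolated: one bad entry never aborts the batch. With `nproc > 1` entries
#' are distributed over processes; outputs are identical to serial execution.
#'
#' @param ids character vector of PDB ids (already resolved; see
#'   [resolveIdentifiers()]).
#' @param formats subset of `c("mmCIF", "PDB", "mmCIF_assembly",
#'   "PDB_assembly")`; default mmCIF.
#' @param paths directory layout, see [defaultPaths()].
#' @param offsets an [OffsetConfig-class].
#' @param exceptions,uniprotNames see [resolveChainAccession()].
#' @param gzip gzip outputs (disable with the CLI's `-offz`).
#' @param nproc worker processes.
#' @param fetch fetch missing inputs over the network (FALSE: inputs must
#'   already be in the input directories).
#' @param fetcher,endpoints see [gatherInputs()].
#' @param logFile path for the TSV log (default `unirenum_log.tsv` under the
#'   first output directory); NA disables.
#' @return list with `results` (per entry x format), `report` (combined
#'   per-chain data.frame), `logFile`, `status` (0 if at least one entry
#'   succeeded, 2 if all failed).
#' @export
runBatch <- function(ids, formats = "mmCIF", paths = defaultPaths(),
                     offsets = offsetConfig(),
                     exceptions = chaperoneExceptions(),
                     uniprotNames = character(), gzip = TRUE, nproc = 1L,
                     fetch = FALSE, fetcher = defaultFetcher(),
                     endpoints = defaultEndpoints(), logFile = NULL) {
    formats <- match.arg(formats, c("mmCIF", "PDB", "mmCIF_assembly",
                                    "PDB_assembly"), several.ok = TRUE)
    ids <- tolower(ids)
    if (fetch)
        gatherInputs(ids, formats, paths, endpoints, fetcher = fetcher)

    inputPath <- function(id, kind) {
        fname <- switch(kind,
            mmCIF = paste0(id, ".cif.gz"), PDB = paste0(id, ".pdb.gz"),
            mmCIF_assembly = sprintf("%s-assembly-1.cif.gz", id),
            PDB_assembly = sprintf("%s.pdb1.gz", id))
        cands <- file.path(paths[[kind]],
                           c(fname, sub("\\.gz$", "", fname)))
        cands[file.exists(cands)][1L]
    }
    siftsPath <- function(id) {
        cands <- file.path(paths$SIFTS, paste0(id, c(".xml.gz", ".xml")))
        hit <- cands[file.exists(cands)]
        if (length(hit)) hit[1L] else NA_character_
    }

    jobs <- expand.grid(id = ids, kind = formats, stringsAsFactors = FALSE)
    worker <- function(j) {
        id <- jobs$id[j]
        kind <- jobs$kind[j]
        format <- if (startsWith(kind, "mmCIF")) "mmcif" else "legacy"
        assembly <- if (grepl("assembly", kind)) 1L else NA
        sp <- inputPath(id, kind)
        tryCatch({
            if (is.na(sp) || !length(sp))
                list(id = id, kind = kind, status = "failed",
                     outPath = NA_character_, report = emptyReport(),
                     message = "structure input not found")
            else
                c(renumberEntry(id, sp, siftsPath(id), format,
                                paths[[paste0("output_", kind)]], offsets,
                                exceptions, uniprotNames, gzip, assembly),
                  list(kind = kind))
        }, error = function(e)
            list(id = id, kind = kind, status = "failed",
                 outPath = NA_character_, report = emptyReport(),
                 message = conditionMessage(e)))
    }
    results <- if (nproc > 1L && .Platform$OS.type == "unix")
        parallel::mclapply(seq_len(nrow(jobs)), worker, mc.cores = nproc,
                           mc.preschedule = TRUE)
    else lapply(seq_len(nrow(jobs)), worker)

    report <- do.call(rbind, c(list(emptyReport()),
                               lapply(results, `[[`, "report")))
    if (is.null(logFile)) {
        outdirs <- unlist(paths[paste0("output_", formats)])
        dir.create(outdirs[1L], showWarnings = FALSE, recursive = TRUE)
        logFile <- file.path(outdirs[1L], "unirenum_log.tsv")
    }
    if (!is.na(logFile))
        utils::write.table(report, logFile, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    ok <- vapply(results, function(r) r$status %in% c("ok", "no_sifts",
                                                      "no_uniprot"),
                 logical(1L))
    list(results = results, report = report, logFile = logFile,
         status = if (any(ok)) 0L else 2L)
}
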