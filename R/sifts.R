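#' Parse a SIFTS per-entry residue mapping into a residue table
#'
#' Reads the residue-level XML distributed by PDBe for one PDB entry and
#' returns one row per polymer residue, linking the canonical 1-to-N position
#' of each protein chain to the author numbering used in the coordinates and,
#' where SIFTS provides one, to a UniProt accession and residue number.
#'
#' Author numbers carrying a trailing uppercase letter are split into the
#' integer number and the insertion code. Residues not observed in the
#' coordinates (author number "null" in SIFTS) get `NA` in `auth_res_num`.
#' Residues SIFTS annotates as mutated or conflicting relative to the UniProt
#' sequence have `is_mutation = TRUE`; their structure residue name and
#' UniProt number are both retained downstream.
#'
#' @param source path to a SIFTS XML file (plain or gzipped), or a single
#'   character string containing the XML.
#' @return data.frame with columns `pdb_chain_id` (SIFTS entityId /
#'   mmCIF label_asym_id), `auth_chain_id`, `seq_res_num`, `auth_res_num`,
#'   `ins_code`, `res_name`, `accession`, `uniprot_res_num`,
#'   `uniprot_res_name`, `is_mutation`.
#' @examples
#' fx <- makeFixture(fixtureSpec(chainLength = 5), seed = 1)
#' head(parseSifts(fx$sifts_xml))
#' @export
parseSifts <- function(source) {
    doc <- tryCatch(xml2::read_xml(source), error = function(e) {
        stop("malformed SIFTS XML (", conditionMessage(e), ")", call. = FALSE)
    })
    xml2::xml_ns_strip(doc)
    entry <- xml2::xml_attr(doc, "dbAccessionId")
    if (is.na(entry)) entry <- "<unknown>"

    entities <- xml2::xml_find_all(doc, ".//entity[@type='protein']")
    out <- vector("list", length(entities))
    for (i in seq_along(entities)) {
        ent <- entities[[i]]
        pdb_chain <- xml2::xml_attr(ent, "entityId")
        residues <- xml2::xml_find_all(ent, ".//segment/listResidue/residue")
        if (!length(residues)) next

        seqnum <- parseIntStrict(xml2::xml_attr(residues, "dbResNum"))

        pdbref <- xml2::xml_find_first(residues, "crossRefDb[@dbSource='PDB']")
        authraw <- xml2::xml_attr(pdbref, "dbResNum")
        authchain <- xml2::xml_attr(pdbref, "dbChainId")
        resname <- xml2::xml_attr(pdbref, "dbResName")

        uniref <- xml2::xml_find_first(residues,
                                       "crossRefDb[@dbSource='UniProt']")
        acc <- xml2::xml_attr(uniref, "dbAccessionId")
        uninum <- parseIntStrict(xml2::xml_attr(uniref, "dbResNum"))
        uniname <- xml2::xml_attr(uniref, "dbResName")

        ann <- xml2::xml_find_first(
            residues, "residueDetail[@property='Annotation']")
        anntext <- xml2::xml_text(ann)
        mut <- !is.na(anntext) &
            grepl("mutation|conflict", anntext, ignore.case = TRUE)

        # author numbers: "null" -> unobserved; trailing A-Z -> insertion code
        authraw[is.na(authraw)] <- "null"
        isnull <- tolower(authraw) == "null"
        ins <- rep("", length(authraw))
        core <- authraw
        hasins <- grepl("^-?[0-9]+[A-Z]$", authraw)
        ins[hasins] <- substring(authraw[hasins], nchar(authraw[hasins]))
        core[hasins] <- substring(authraw[hasins], 1L,
                                  nchar(authraw[hasins]) - 1L)
        authnum <- rep(NA_integer_, length(core))
        okint <- grepl("^-?[0-9]+$", core) & !isnull
        authnum[okint] <- as.integer(core[okint])
        bad <- !isnull & !okint
        if (any(bad))
            stop(sprintf(
                "entry %s: non-integer author residue number %s at chain %s position %s",
                entry, sQuote(authraw[bad][1L]), pdb_chain,
                seqnum[bad][1L]), call. = FALSE)

        out[[i]] <- data.frame(
            pdb_chain_id = pdb_chain,
            auth_chain_id = ifelse(is.na(authchain), pdb_chain, authchain),
            seq_res_num = seqnum,
            auth_res_num = authnum,
            ins_code = ins,
            res_name = ifelse(is.na(resname), "UNK", resname),
            accession = acc,
            uniprot_res_num = uninum,
            uniprot_res_name = uniname,
            is_mutation = mut,
            stringsAsFactors = FALSE)
    }
    out <- out[!vapply(out, is.null, logical(1L))]
    if (!length(out)) return(emptyResidueRecords())
    rec <- do.call(rbind, out)
    # a UniProt number without an accession (or vice versa) is inconsistent
    rec$uniprot_res_num[is.na(rec$accession)] <- NA_integer_
    rec$uniprot_res_name[is.na(rec$accession)] <- NA_character_
    rec$accession[is.na(rec$uniprot_res_num)] <- NA_character_
    rownames(rec) <- NULL
    rec
}

#' Default crystallization-chaperone exception list
#'
#' UniProt sequences commonly used as crystallization chaperones or fusion
#' partners; when a chimeric chain's numbering clashes, these are skipped in
#' favour of the study target even when they cover more residues. The default
#' list is read from a plain-text config shipped with the package
#' (`extdata/chaperone_exceptions.txt`), one identifier per line; identifiers
#' may be in SwissProt ID form (GFP_AEQVI) or accession form.
#'
#' @param path optional path to an alternative exception list.
#' @return character vector of identifiers.
#' @examples
#' chaperoneExceptions()
#' @export
chaperoneExceptions <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "chaperone_exceptions.txt",
                            package = "unirenum", mustWork = TRUE)
    x <- readLines(path, warn = FALSE)
    x <- trimws(sub("#.*$", "", x))
    x[nzchar(x)]
}

#' Choose the accession(s) that renumber each chain
#'
#' Most chains map to a single UniProt accession. Chimeric chains map to
#' several; when their UniProt number ranges do not overlap, every segment is
#' renumbered by its own accession (flag "+"). When the ranges clash, the
#' accession covering the most residues wins (flag "*"), unless it is on the
#' crystallization-chaperone exception list, in which case the
#' largest-coverage non-excepted accession is taken. Coverage ties break to
#' the lexicographically smallest accession so output is deterministic.
#' Chains with no UniProt rows keep no accession and are left untouched by
#' the renumbering engines.
#'
#' @param records residue table from [parseSifts()].
#' @param exceptions identifiers to skip on clash; default
#'   [chaperoneExceptions()].
#' @param uniprotNames optional named character vector mapping accession ->
#'   SwissProt-style ID, used for reporting and for matching ID-form
#'   exceptions.
#' @return A [ChainAccessionMap-class].
#' @examples
#' fx <- makeFixture(fixtureSpec(chainLength = 10), seed = 1)
#' resolveChainAccession(parseSifts(fx$sifts_xml))
#' @export
resolveChainAccession <- function(records, exceptions = chaperoneExceptions(),
                                  uniprotNames = character()) {
    chains <- unique(records$auth_chain_id)
    rows <- vector("list", length(chains))
    active <- stats::setNames(vector("list", length(chains)), chains)
    coverage <- stats::setNames(vector("list", length(chains)), chains)

    for (i in seq_along(chains)) {
        ch <- chains[i]
        sub <- records[records$auth_chain_id == ch & !is.na(records$accession), ]
        cand <- sort(unique(sub$accession))
        cov <- vapply(cand, function(a) sum(sub$accession == a), integer(1L))
        coverage[[ch]] <- cov
        flag <- ""
        if (length(cand) == 0L) {
            act <- character()
        } else if (length(cand) == 1L) {
            act <- cand
        } else {
            rng <- lapply(cand, function(a) {
                range(sub$uniprot_res_num[sub$accession == a], na.rm = TRUE)
            })
            clash <- FALSE
            for (a in seq_along(cand))
                for (b in seq_along(cand))
                    if (a < b && rng[[a]][1L] <= rng[[b]][2L] &&
                        rng[[b]][1L] <= rng[[a]][2L]) clash <- TRUE
            if (!clash) {
                act <- cand
                flag <- "+"
            } else {
                # coverage desc, accession asc; skip chaperones if possible
                ord <- order(-cov, cand)
                ids <- uniprotNames[cand[ord]]
                excepted <- cand[ord] %in% exceptions |
                    (!is.na(ids) & ids %in% exceptions)
                pick <- if (all(excepted)) cand[ord][1L] else
                    cand[ord][!excepted][1L]
                act <- pick
                flag <- "*"
            }
        }
        active[[ch]] <- act
        sp <- uniprotNames[act]
        rows[[i]] <- data.frame(
            auth_chain_id = ch,
            pdb_chain_id = records$pdb_chain_id[records$auth_chain_id == ch][1L],
            flag = flag,
            accession = paste(act, collapse = ","),
            n_candidates = length(cand),
            stringsAsFactors = FALSE)
    }
    sp <- uniprotNames[!is.na(names(uniprotNames))]
    new("ChainAccessionMap",
        chains = if (length(rows)) do.call(rbind, rows) else
            data.frame(auth_chain_id = character(), pdb_chain_id = character(),
                       flag = character(), accession = character(),
                       n_candidates = integer(), stringsAsFactors = FALSE),
        active = active, coverage = coverage,
        swissprot = if (length(sp)) sp else character())
}
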