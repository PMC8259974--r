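# Legacy (fixed-column, 80-character) PDB format renumbering.
#
# wwPDB v3.3 columns (1-based): resName 18-20, chainID 22, resSeq 23-26,
# iCode 27 on coordinate-style records; REMARK 465 data rows carry resName
# 16-18, chainID 20, number 21-26, iCode 27. Substitution is key-targeted
# column rewriting, never global text replacement, so coincidental matches
# elsewhere on a line can never be corrupted.

COORD_KINDS <- c("ATOM", "HETATM", "TER", "ANISOU", "SIGUIJ")

#' Classify a legacy PDB line and extract its residue key
#'
#' Coordinate-style records (`ATOM`, `HETATM`, `TER`, `ANISOU`, `SIGUIJ`)
#' yield the 9-character key `AuthResNum(4) + InsCode(1) + ResName(3) +
#' ChainID(1)` read from the coordinate columns; `REMARK 465` data rows yield
#' the same key read from the remark columns. Header and other lines yield no
#' key. A coordinate line whose residue-number field is not an integer is
#' classified but yields no key (it will pass through unmodified).
#'
#' @param line one line of a legacy PDB file.
#' @return list with `kind` (one of `"ATOM"`, `"HETATM"`, `"TER"`,
#'   `"ANISOU"`, `"SIGUIJ"`, `"REMARK465"`, `"other"`), and for keyed lines
#'   `key` (9-character string), `num`, `ins`, `res`, `chain`.
#' @examples
#' classifyAndExtract(
#'   "ATOM      1  CA  ALA A 100      11.000  12.000  13.000  1.00 20.00           C")
#' @export
classifyAndExtract <- function(line) {
    rec <- trimws(substr(line, 1L, 6L))
    if (rec %in% COORD_KINDS) {
        num <- substr(line, 23L, 26L)
        ins <- substr(line, 27L, 27L)
        res <- substr(line, 18L, 20L)
        chain <- substr(line, 22L, 22L)
        if (is.na(parseIntStrict(num)))
            return(list(kind = rec, key = NULL))
        return(list(kind = rec,
                    key = legacyKey(num, ins, res, chain),
                    num = parseIntStrict(num), ins = normalizeIns(ins),
                    res = trimws(res), chain = chain))
    }
    if (startsWith(line, "REMARK 465")) {
        num <- substr(line, 21L, 26L)
        if (is.na(parseIntStrict(num)))
            return(list(kind = "REMARK465", key = NULL))
        ins <- substr(line, 27L, 27L)
        res <- substr(line, 16L, 18L)
        chain <- substr(line, 20L, 20L)
        return(list(kind = "REMARK465",
                    key = legacyKey(sprintf("%4d", parseIntStrict(num)),
                                    ins, res, chain),
                    num = parseIntStrict(num), ins = normalizeIns(ins),
                    res = trimws(res), chain = chain))
    }
    list(kind = "other", key = NULL)
}

#' Reassign non-polymer residue numbers from the top of the legacy range
#'
#' The legacy format caps residue numbers at 9999, so ligand numbers cannot
#' be offset the way mmCIF output does it. Instead, the numbers still
#' available in 1..9999 after the polymer chains are renumbered are handed to
#' the non-polymer groups in reverse order: the first group (in file order)
#' gets the largest free number, and so on.
#'
#' @param usedNumbers integer vector of numbers already taken by polymer
#'   residues.
#' @param nGroups how many non-polymer groups need numbers.
#' @return integer vector of length `nGroups`, strictly decreasing.
#' @examples
#' reassignHeteroNumbers(1:150, 1)     # -> 9999
#' reassignHeteroNumbers(c(1:150, 9999), 2)  # -> 9998 9997
#' @export
reassignHeteroNumbers <- function(usedNumbers, nGroups) {
    if (nGroups == 0L) return(integer())
    avail <- setdiff(9999:1, unique(as.integer(usedNumbers)))
    if (length(avail) < nGroups)
        stop("no residue numbers left in 1..9999 to reassign ", nGroups,
             " non-polymer group(s)", call. = FALSE)
    avail[seq_len(nGroups)]
}

legacyRemarkText <- function(offsets) {
    c("REMARK   0 FILE RENUMBERED TO UNIPROT NUMBERING BY UNIRENUM.",
      "REMARK   0 AUTHOR SEQUENCE NUMBERING IS REPLACED WITH UNIPROT NUMBERING",
      "REMARK   0 ACCORDING TO ALIGNMENT BY SIFTS",
      "REMARK   0 (HTTPS://WWW.EBI.AC.UK/PDBE/DOCS/SIFTS/).",
      "REMARK   0 ONLY CHAINS WITH UNIPROT SEQUENCES IN SIFTS ARE RENUMBERED.",
      "REMARK   0 RESIDUES IN UNIPROT CHAINS WITHOUT UNIPROT RESIDUE NUMBERS IN",
      sprintf("REMARK   0 SIFTS (E.G., SEQUENCE TAGS) ARE GIVEN RESIDUE NUMBERS %d+N",
              offsets@legacy),
      "REMARK   0 (WHERE N IS THE 1-TO-N RESIDUE NUMBERING OF EACH CHAIN).",
      "REMARK   0 LIGANDS ARE REASSIGNED THE LARGEST RESIDUE NUMBERS STILL FREE",
      "REMARK   0 IN 1..9999, IN REVERSE ORDER.")
}

# rewrite the number (and insertion-code) columns of one line in place
rewriteLineNumber <- function(line, new, kind) {
    newnum <- substr(new, 1L, 4L)
    newins <- substr(new, 5L, 5L)
    if (kind == "REMARK465") {
        paste0(substr(line, 1L, 20L), sprintf("%6d", parseIntStrict(newnum)),
               newins, substring(line, 28L))
    } else {
        paste0(substr(line, 1L, 22L), newnum, newins, substring(line, 28L))
    }
}

#' Renumber the lines of a legacy PDB file
#'
#' Every line whose extracted 9-character key is present in the replacement
#' map has exactly its residue-number and insertion-code columns rewritten at
#' identical width; all other columns and all unmatched lines are untouched.
#' `REMARK 465` rows for residues that have no author number in the mapping
#' (unobserved residues) are matched per chain, in file order, against the
#' map's unobserved-residue records, requiring residue-name agreement. The
#' provenance `REMARK 0` block is inserted at the top.
#'
#' @param lines character vector of legacy PDB lines.
#' @param map a legacy-format [ReplacementMap-class] whose `auth` slot may be
#'   augmented with non-polymer keys (see [renumberLegacy()] for the full
#'   pipeline).
#' @param remarkText lines to insert at the top (default generated from
#'   `offsets`).
#' @param offsets an [OffsetConfig-class] (used only for the remark text).
#' @return character vector of renumbered lines, with attribute
#'   `"unmatched"`: the number of keyed lines that found no replacement.
#' @export
renumberLegacyLines <- function(lines, map,
                                remarkText = legacyRemarkText(offsets),
                                offsets = offsetConfig()) {
    missPool <- split(map@missing, map@missing$auth_chain_id)
    missUsed <- stats::setNames(integer(length(missPool)), names(missPool))
    unmatched <- 0L
    out <- vapply(lines, function(line) {
        ce <- classifyAndExtract(line)
        if (is.null(ce$key)) return(line)
        new <- map@auth[ce$key]
        if (!is.na(new)) return(rewriteLineNumber(line, new, ce$kind))
        if (ce$kind == "REMARK465" && ce$chain %in% names(missPool)) {
            pool <- missPool[[ce$chain]]
            nxt <- missUsed[[ce$chain]] + 1L
            if (nxt <= nrow(pool) && pool$res_name[nxt] == ce$res) {
                missUsed[[ce$chain]] <<- nxt
                val <- paste0(sprintf("%4d", pool$new_number[nxt]),
                              if (nzchar(ce$ins)) ce$ins else " ")
                return(rewriteLineNumber(line, val, ce$kind))
            }
        }
        unmatched <<- unmatched + 1L
        line
    }, "", USE.NAMES = FALSE)
    out <- c(remarkText, out)
    attr(out, "unmatched") <- unmatched
    out
}

#' Renumber a legacy PDB file end to end
#'
#' Builds the fixed-width replacement map from a legacy-format plan, assigns
#' reverse-order numbers to the non-polymer groups found in the file (first
#' `HETATM` group in file order gets the largest free number), applies the
#' substitution line by line, and inserts the provenance remark.
#'
#' @param lines character vector of legacy PDB lines.
#' @param plan a legacy-format [RenumberPlan-class].
#' @param offsets an [OffsetConfig-class].
#' @return renumbered lines (attribute `"unmatched"` as in
#'   [renumberLegacyLines()]).
#' @export
renumberLegacy <- function(lines, plan, offsets = plan@offsets) {
    if (nrow(planResidues(plan)) == 0L) {
        attr(lines, "unmatched") <- 0L
        return(lines)
    }
    map <- buildReplacementMap(plan, "legacy")

    # non-polymer groups: HETATM residues not covered by the polymer map
    groups <- character()
    ginfo <- list()
    for (line in lines) {
        ce <- classifyAndExtract(line)
        if (is.null(ce$key) || ce$kind != "HETATM") next
        if (ce$key %in% names(map@auth)) next
        gid <- ce$key
        if (!gid %in% groups) {
            groups <- c(groups, gid)
            ginfo[[gid]] <- ce
        }
    }
    used <- planResidues(plan)$new_number
    if (length(groups)) {
        newnums <- reassignHeteroNumbers(used, length(groups))
        het <- stats::setNames(vapply(seq_along(groups), function(i) {
            ce <- ginfo[[groups[i]]]
            legacyKey(newnums[i], ce$ins, sprintf("%3s", ce$res), ce$chain)
        }, ""), groups)
        map@auth <- c(map@auth, het)
    }
    renumberLegacyLines(lines, map, offsets = offsets)
}

#' Write legacy PDB lines
#'
#' @param lines character vector of lines.
#' @param path output path; gzip-compressed when `gzip = TRUE`.
#' @param gzip compress the output.
#' @return the path, invisibly.
#' @export
writeLegacy <- function(lines, path, gzip = TRUE) {
    con <- if (gzip) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    writeLines(c(lines), con)
    invisible(path)
}

#' Read legacy PDB lines
#'
#' @param path a `.pdb` or `.pdb.gz` file.
#' @return character vector of lines.
#' @export
readLegacy <- function(path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    readLines(con, warn = FALSE)
}
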