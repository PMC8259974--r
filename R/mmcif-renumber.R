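# Renumbering of mmCIF categories.
#
# Every item below is a dictionary child of _atom_site.auth_seq_id (or, for
# the scheme tables, the pdb_seq_num that mirrors it), vetted against the
# PDBx/mmCIF dictionary; each is renumbered through the same
# (author number, insertion code, author chain) key as the coordinates.

RENUMBERABLE_ITEMS <- c(
    "_atom_site_anisotrop.pdbx_auth_seq_id",
    "_atom_site.auth_seq_id",
    "_pdbx_distant_solvent_atoms.auth_seq_id",
    "_pdbx_refine_tls_group.beg_auth_seq_id",
    "_pdbx_refine_tls_group.end_auth_seq_id",
    "_pdbx_struct_chem_comp_diagnostics.auth_seq_id",
    "_pdbx_struct_conn_angle.ptnr1_auth_seq_id",
    "_pdbx_struct_conn_angle.ptnr2_auth_seq_id",
    "_pdbx_struct_conn_angle.ptnr3_auth_seq_id",
    "_pdbx_struct_mod_residue.auth_seq_id",
    "_pdbx_struct_sheet_hbond.range_1_auth_seq_id",
    "_pdbx_struct_sheet_hbond.range_2_auth_seq_id",
    "_pdbx_struct_special_symmetry.auth_seq_id",
    "_pdbx_unobs_or_zero_occ_atoms.auth_seq_id",
    "_pdbx_unobs_or_zero_occ_residues.auth_seq_id",
    "_pdbx_validate_chiral.auth_seq_id",
    "_pdbx_validate_close_contact.auth_seq_id_1",
    "_pdbx_validate_close_contact.auth_seq_id_2",
    "_pdbx_validate_main_chain_plane.auth_seq_id",
    "_pdbx_validate_peptide_omega.auth_seq_id_1",
    "_pdbx_validate_peptide_omega.auth_seq_id_2",
    "_pdbx_validate_planes.auth_seq_id",
    "_pdbx_validate_polymer_linkage.auth_seq_id_1",
    "_pdbx_validate_polymer_linkage.auth_seq_id_2",
    "_pdbx_validate_rmsd_angle.auth_seq_id_1",
    "_pdbx_validate_rmsd_angle.auth_seq_id_2",
    "_pdbx_validate_rmsd_angle.auth_seq_id_3",
    "_pdbx_validate_rmsd_bond.auth_seq_id_1",
    "_pdbx_validate_rmsd_bond.auth_seq_id_2",
    "_pdbx_validate_symm_contact.auth_seq_id_1",
    "_pdbx_validate_symm_contact.auth_seq_id_2",
    "_pdbx_validate_torsion.auth_seq_id",
    "_struct_conf.beg_auth_seq_id",
    "_struct_conf.end_auth_seq_id",
    "_struct_conn.ptnr1_auth_seq_id",
    "_struct_conn.ptnr2_auth_seq_id",
    "_struct_mon_prot_cis.auth_seq_id",
    "_struct_mon_prot_cis.pdbx_auth_seq_id_2",
    "_struct_ncs_dom_lim.beg_auth_seq_id",
    "_struct_ncs_dom_lim.end_auth_seq_id",
    "_struct_sheet_range.beg_auth_seq_id",
    "_struct_sheet_range.end_auth_seq_id",
    "_struct_site_gen.auth_seq_id",
    "_struct_site.pdbx_auth_seq_id",
    "_pdbx_nonpoly_scheme.pdb_seq_num",
    "_pdbx_nonpoly_seq_scheme.pdb_seq_num",
    "_pdbx_poly_seq_scheme.pdb_seq_num",
    "_pdbx_branch_scheme.pdb_seq_num",
    "_struct_ref_seq_dif.pdbx_auth_seq_num",
    "_struct_ref_seq.pdbx_auth_seq_align_beg",
    "_struct_ref_seq.pdbx_auth_seq_align_end"
)

CHAIN_ID_TOKENS <- c("auth_asym_id", "pdb_strand_id", "pdbx_strand_id")
INS_CODE_TOKENS <- c("pdbx_PDB_ins_code", "PDB_ins_code", "pdb_ins_code",
                     "ins_code")
NUMBER_TOKENS <- c("auth_seq_align_beg", "auth_seq_align_end", "auth_seq_num",
                   "auth_seq_id", "pdb_seq_num")

itemRole <- function(category) {
    switch(category,
           "_atom_site" = "coordinate",
           "_pdbx_poly_seq_scheme" = "scheme",
           "_pdbx_nonpoly_seq_scheme" = ,
           "_pdbx_nonpoly_scheme" = ,
           "_pdbx_branch_scheme" = "nonpoly-scheme",
           "annotation")
}

# locate the chain-id / ins-code companion of a residue-number column
findCompanion <- function(cols, numberItem, tokens) {
    tok <- NUMBER_TOKENS[vapply(NUMBER_TOKENS, grepl, TRUE, x = numberItem,
                                fixed = TRUE)][1L]
    pos <- regexpr(tok, numberItem, fixed = TRUE)
    pre <- substr(numberItem, 1L, pos - 1L)
    suf <- substring(numberItem, pos + nchar(tok))

    # exact prefix/suffix composition first, allowing pdbx_ to come and go
    pres <- unique(c(pre, sub("^pdbx_", "", pre), paste0("pdbx_", pre)))
    for (p in pres)
        for (t in tokens) {
            cand <- paste0(p, t, suf)
            if (cand %in% cols) return(cand)
        }
    hits <- cols[Reduce(`|`, lapply(tokens, function(t) grepl(t, cols,
                                                              fixed = TRUE)))]
    if (nzchar(suf)) hits <- hits[endsWith(hits, suf)]
    if (length(hits) > 1L && nzchar(pre)) {
        scored <- hits[grepl(gsub("_$", "", pre), hits, fixed = TRUE)]
        if (length(scored)) hits <- scored
    }
    if (length(hits) >= 1L) hits[1L] else NA_character_
}

#' Enumerate the residue-numbered items present in a document
#'
#' Intersects the vetted static list of author-residue-number items (children
#' of `_atom_site.auth_seq_id` per the PDBx/mmCIF dictionary, plus
#' `pdb_seq_num` in the three sequence-scheme tables and
#' `_struct_ref_seq_dif.pdbx_auth_seq_num`) with the categories present in
#' `doc`, pairing each with its author chain-id column (any `auth_asym_id` /
#' `pdb_strand_id` / `pdbx_strand_id` variant) and insertion-code column.
#' Items whose chain-id companion is missing are skipped with a warning.
#'
#' @param doc an [MmcifDocument-class].
#' @return data.frame with columns `category`, `number_item`, `chain_item`,
#'   `ins_item` (NA when the table carries no insertion codes), `role`.
#' @export
enumerateRenumberableItems <- function(doc) {
    present <- cifCategories(doc)
    out <- list()
    for (full in RENUMBERABLE_ITEMS) {
        p <- strsplit(full, ".", fixed = TRUE)[[1L]]
        cat <- p[1L]
        item <- paste(p[-1L], collapse = ".")
        if (!cat %in% present) next
        tb <- cifTable(doc, cat)
        if (!item %in% names(tb)) next
        chain <- findCompanion(names(tb), item, CHAIN_ID_TOKENS)
        if (is.na(chain)) {
            warning("item ", full, " has no chain-id companion column; skipped",
                    call. = FALSE)
            next
        }
        ins <- findCompanion(names(tb), item, INS_CODE_TOKENS)
        out[[length(out) + 1L]] <- data.frame(
            category = cat, number_item = item, chain_item = chain,
            ins_item = ins, role = itemRole(cat), stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(category = character(), number_item = character(),
                          chain_item = character(), ins_item = character(),
                          role = character(), stringsAsFactors = FALSE))
    do.call(rbind, out)
}

# ligand numbers: every non-polymer (HETATM / scheme) residue not covered by
# the polymer map receives ligand offset + its original number
ligandLookup <- function(doc, map, offsets) {
    env <- new.env(parent = emptyenv())
    # an entry with nothing to renumber keeps its ligands untouched too
    if (!length(map@auth) && !length(map@seq)) return(env)
    addKeys <- function(num, ins, chain) {
        ins <- rep(normalizeIns(ins), length.out = length(num))
        ok <- !is.na(parseIntStrict(num))
        keys <- mmcifKey(num[ok], ins[ok], chain[ok])
        new <- offsets@ligandMmcif + parseIntStrict(num[ok])
        # ligand author numbers may coincide with polymer numbers on the same
        # chain; rows are routed here only when known to be non-polymer
        for (i in seq_along(keys)) assign(keys[i], as.character(new[i]), env)
    }
    for (cat in c("_pdbx_nonpoly_seq_scheme", "_pdbx_nonpoly_scheme",
                  "_pdbx_branch_scheme")) {
        tb <- cifTable(doc, cat)
        if (is.null(tb)) next
        insc <- if ("pdb_ins_code" %in% names(tb)) tb$pdb_ins_code else ""
        addKeys(tb$pdb_seq_num, insc, tb$pdb_strand_id)
    }
    as_ <- cifTable(doc, "_atom_site")
    if (!is.null(as_)) {
        het <- (if ("group_PDB" %in% names(as_)) as_$group_PDB == "HETATM"
                else FALSE) |
            (if ("label_seq_id" %in% names(as_))
                as_$label_seq_id %in% c(".", "?") else FALSE)
        if (any(het)) {
            insc <- if ("pdbx_PDB_ins_code" %in% names(as_))
                as_$pdbx_PDB_ins_code[het] else ""
            addKeys(as_$auth_seq_id[het], insc, as_$auth_asym_id[het])
        }
    }
    env
}

#' Renumber every residue-numbered item of an mmCIF document
#'
#' Applies the replacement map to every enumerated item except the
#' sequence-scheme tables (which [rewriteSeqScheme()] owns, because they also
#' archive the original numbering). Rows whose key is absent from the map are
#' left unchanged, except non-polymer rows (ligands, waters, branched
#' sugars), which receive `ligand offset + original number`. Null markers
#' ("." and "?") and every other column pass through byte-identically.
#'
#' @param doc an [MmcifDocument-class].
#' @param map a mmCIF-format [ReplacementMap-class].
#' @param plan the [RenumberPlan-class] the map came from.
#' @param offsets an [OffsetConfig-class].
#' @return the renumbered document, with attribute `"unmatched"` counting
#'   polymer keys that found no replacement per category.
#' @export
renumberDocument <- function(doc, map, plan, offsets = offsetConfig()) {
    if (map@format != "mmcif")
        stop("renumberDocument needs a mmCIF-format map", call. = FALSE)
    lig <- ligandLookup(doc, map, offsets)
    items <- enumerateRenumberableItems(doc)
    unmatched <- integer()
    for (r in seq_len(nrow(items))) {
        it <- items[r, ]
        if (it$role %in% c("scheme", "nonpoly-scheme")) next
        tb <- cifTable(doc, it$category)
        num <- tb[[it$number_item]]
        ins <- if (!is.na(it$ins_item)) tb[[it$ins_item]] else ""
        chain <- tb[[it$chain_item]]
        keys <- mmcifKey(num, ins, chain)
        ligGet <- function(kk) vapply(kk, function(k)
            if (exists(k, envir = lig, inherits = FALSE))
                get(k, envir = lig) else NA_character_, "")
        # rows known to be non-polymer take the ligand rule even when their
        # author number coincides with a polymer residue's
        nonpoly <- if (it$category == "_atom_site") {
            (if ("label_seq_id" %in% names(tb))
                 tb$label_seq_id %in% c(".", "?") else FALSE) |
            (if ("group_PDB" %in% names(tb))
                 tb$group_PDB == "HETATM" else FALSE)
        } else rep(FALSE, length(num))
        new <- rep(NA_character_, length(num))
        new[!nonpoly] <- unname(map@auth[keys[!nonpoly]])
        new[nonpoly] <- ligGet(keys[nonpoly])
        fromlig <- is.na(new) & !nonpoly
        new[fromlig] <- ligGet(keys[fromlig])
        skip <- num %in% c(".", "?")
        hit <- !is.na(new) & !skip
        num[hit] <- new[hit]
        # residues of renumbered chains should all match; count strays
        poly <- chain %in% planChains(plan)$auth_chain_id & !skip
        unmatched[it$category] <- sum(poly & is.na(new)) +
            sum(unmatched[it$category], na.rm = TRUE)
        tb[[it$number_item]] <- num
        cifTable(doc, it$category) <- tb
    }
    attr(doc, "unmatched") <- unmatched
    doc
}

#' Rewrite the sequence-scheme tables, preserving original numbering
#'
#' In `_pdbx_poly_seq_scheme`, `_pdbx_nonpoly_seq_scheme` and
#' `_pdbx_branch_scheme`, `pdb_seq_num` is renumbered (UniProt / offset for
#' polymers, ligand offset for non-polymers) and the original `pdb_seq_num`
#' values are written into `auth_seq_num`, discarding the historical values
#' kept there. The result is a three-way correspondence between the 1-to-N
#' numbering (`seq_id`), the new numbering, and the numbering of the original
#' file. Unobserved polymer residues are matched through their `seq_id`.
#' Absent tables are a no-op.
#'
#' @inheritParams renumberDocument
#' @return the document with rewritten scheme tables.
#' @export
rewriteSeqScheme <- function(doc, map, offsets = offsetConfig()) {
    lig <- ligandLookup(doc, map, offsets)
    for (cat in c("_pdbx_poly_seq_scheme", "_pdbx_nonpoly_seq_scheme",
                  "_pdbx_nonpoly_scheme", "_pdbx_branch_scheme")) {
        tb <- cifTable(doc, cat)
        if (is.null(tb) || !"pdb_seq_num" %in% names(tb)) next
        orig <- tb$pdb_seq_num
        ins <- if ("pdb_ins_code" %in% names(tb)) tb$pdb_ins_code else ""
        chain <- if ("pdb_strand_id" %in% names(tb)) tb$pdb_strand_id else
            tb[[findCompanion(names(tb), "pdb_seq_num", CHAIN_ID_TOKENS)]]
        keys <- mmcifKey(orig, ins, chain)
        if (cat == "_pdbx_poly_seq_scheme") {
            new <- unname(map@auth[keys])
            miss <- is.na(new)
            if ("seq_id" %in% names(tb)) {
                skeys <- seqKey(chain[miss], trimws(tb$seq_id[miss]))
                new[miss] <- unname(map@seq[skeys])
            }
        } else {
            # non-polymer schemes take the ligand rule, never the polymer map
            new <- vapply(keys, function(k)
                if (exists(k, envir = lig, inherits = FALSE))
                    get(k, envir = lig) else NA_character_, "",
                USE.NAMES = FALSE)
        }
        hit <- !is.na(new)
        out <- orig
        out[hit] <- new[hit]
        tb$pdb_seq_num <- out
        if ("auth_seq_num" %in% names(tb)) tb$auth_seq_num <- orig
        cifTable(doc, cat) <- tb
    }
    doc
}

mmcifRemarkText <- function(offsets) {
    paste0(
        "File renumbered to UniProt numbering by unirenum.\n",
        "Author sequence numbering is replaced with UniProt numbering according to\n",
        "alignment by SIFTS (https://www.ebi.ac.uk/pdbe/docs/sifts/).\n",
        "Only chains with UniProt sequences in SIFTS are renumbered.\n",
        "Residues in UniProt chains without UniProt residue numbers in SIFTS\n",
        sprintf("(e.g., sequence tags) are given residue numbers %d+label_seq_id\n",
                offsets@mmcif),
        "(where label_seq_id is the 1-to-N residue numbering of each chain.\n",
        sprintf("Ligands are numbered %d+their residue number in the original file.\n",
                offsets@ligandMmcif),
        "The _poly_seq_scheme table contains a correspondence between the\n",
        "1-to-N sequence (seq_id), the new numbering based on UniProt (pdb_seq_num =\n",
        "auth_seq_id in the _atom_site records), and the author numbering\n",
        "in the original mmCIF file from the PDB (auth_seq_num).")
}

#' Insert the provenance remark into an mmCIF document
#'
#' Adds a `_database_PDB_remark` record describing the renumbering, with the
#' offset values substituted from the active configuration so the remark
#' always states what was actually done. If a remark from a previous run is
#' already present, a second one is appended and a warning raised — output
#' that has already been renumbered should not be renumbered again.
#'
#' @param doc an [MmcifDocument-class].
#' @param offsets an [OffsetConfig-class].
#' @return the document with the remark table.
#' @export
insertRemark <- function(doc, offsets = offsetConfig()) {
    txt <- mmcifRemarkText(offsets)
    prior <- cifTable(doc, "_database_PDB_remark")
    if (!is.null(prior) &&
        any(grepl("renumbered to UniProt numbering", prior$text %||% ""))) {
        warning("document already carries a renumbering remark; ",
                "it appears to have been renumbered before", call. = FALSE)
        for (i in seq_along(doc@tables)) {
            tb <- doc@tables[[i]]
            if (tb$category == "_database_PDB_remark") {
                nid <- max(parseIntStrict(tb$data$id), 0L, na.rm = TRUE) + 1L
                tb$data$id <- c(tb$data$id, as.character(nid))
                tb$data$text <- c(tb$data$text, txt)
                tb$loop <- TRUE
                doc@tables[[i]] <- tb
                return(doc)
            }
        }
    }
    remark <- list(category = "_database_PDB_remark",
                   items = c("id", "text"),
                   data = list(id = "1", text = txt), loop = TRUE)
    cats <- cifCategories(doc)
    at <- if ("_entry" %in% cats) which(cats == "_entry")[1L] else 0L
    doc@tables <- append(doc@tables, list(remark), after = at)
    doc
}

#' Extend a plan to a biological assembly's chains
#'
#' PDBe assembly files give every chain its own unique author chain id, even
#' when chains are symmetry copies. Each assembly chain is matched back to a
#' source chain of the plan by requiring an identical sequence of
#' (author number + insertion code, residue name) along its polymer residues;
#' matched chains inherit the source chain's numbering. Chains that match no
#' source chain are left out (and reported via a warning), mirroring how
#' foreign chains are left untouched.
#'
#' @param plan a [RenumberPlan-class] built from the asymmetric unit.
#' @param doc the assembly [MmcifDocument-class].
#' @return a [RenumberPlan-class] whose chains are the assembly's chains.
#' @export
extendPlanToAssembly <- function(plan, doc) {
    as_ <- cifTable(doc, "_atom_site")
    if (is.null(as_)) stop("assembly document has no _atom_site", call. = FALSE)
    poly <- !(as_$label_seq_id %in% c(".", "?"))
    ins <- if ("pdbx_PDB_ins_code" %in% names(as_))
        normalizeIns(as_$pdbx_PDB_ins_code) else ""
    sig <- paste(as_$auth_seq_id, ins, as_$auth_comp_id, sep = "~")
    chainSig <- function(chain) {
        sel <- poly & as_$auth_asym_id == chain
        unique(sig[sel])
    }
    r <- planResidues(plan)
    robs <- r[!is.na(r$auth_res_num), ]
    srcSig <- lapply(split(robs, robs$auth_chain_id), function(d)
        paste(d$auth_res_num, d$ins_code, d$res_name, sep = "~"))

    chains <- unique(as_$auth_asym_id[poly])
    resout <- list()
    chout <- list()
    unmatched <- character()
    for (ch in chains) {
        cs <- chainSig(ch)
        hit <- NA_character_
        for (src in names(srcSig))
            if (setequal(cs, srcSig[[src]])) { hit <- src; break }
        if (is.na(hit)) { unmatched <- c(unmatched, ch); next }
        ri <- r[r$auth_chain_id == hit, ]
        ri$auth_chain_id <- ch
        resout[[ch]] <- ri
        ci <- planChains(plan)[planChains(plan)$auth_chain_id == hit, ]
        ci$auth_chain_id <- ch
        chout[[ch]] <- ci
    }
    if (length(unmatched))
        warning("assembly chain(s) ", paste(unmatched, collapse = ", "),
                " match no source chain; left unrenumbered", call. = FALSE)
    new("RenumberPlan",
        residues = if (length(resout)) do.call(rbind, resout) else
            planResidues(plan)[0, ],
        chains = if (length(chout)) do.call(rbind, chout) else
            planChains(plan)[0, ],
        format = planFormat(plan), offsets = plan@offsets)
}

#' Renumber one mmCIF document end to end
#'
#' Convenience pipeline: build the replacement map from the plan, renumber
#' every annotation and coordinate item, rewrite the sequence-scheme tables,
#' and insert the provenance remark.
#'
#' @param doc an [MmcifDocument-class].
#' @param plan a mmCIF-format [RenumberPlan-class] (extended to the assembly
#'   chains first when `doc` is an assembly).
#' @param offsets an [OffsetConfig-class].
#' @return the renumbered document.
#' @export
renumberMmcif <- function(doc, plan, offsets = plan@offsets) {
    if (nrow(planResidues(plan)) == 0L) return(doc)
    map <- buildReplacementMap(plan, "mmcif")
    doc <- renumberDocument(doc, map, plan, offsets)
    doc <- rewriteSeqScheme(doc, map, offsets)
    insertRemark(doc, offsets)
}
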