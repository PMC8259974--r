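# Synthetic fixture triples (SIFTS XML + mmCIF + legacy PDB) exhibiting the
# pathological numbering found in the archive: expression tags with negative,
# missing or arbitrary numbers, signal-peptide offsets, insertion codes,
# chimeric chains, ligands. The three files of a triple are mutually
# consistent, and the generator also emits the renumbering it implies, so the
# whole pipeline is testable offline against a known answer.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Describe a synthetic numbering fixture
#'
#' @param chainLength number of polymer residues (including the tag).
#' @param rule author-numbering scenario: `"identity"` (author equals
#'   UniProt), `"constant-offset"` (author = UniProt + `offset`),
#'   `"signal-peptide"` (author numbering of the mature protein, i.e.
#'   UniProt - `offset`, classically 30 residues), `"negative-tag"`
#'   (tag numbered ..,-2,-1), `"insertion-codes"` (residues at `insertAt`
#'   reuse the previous number with codes A, B, ..), `"chimera"` (two
#'   accessions on one chain), `"no-uniprot"` (chain absent from UniProt).
#' @param offset numbering shift used by `"constant-offset"` (author =
#'   UniProt + offset) and `"signal-peptide"` (author = UniProt - offset).
#' @param tagLength length of the N-terminal expression tag (His tag), not
#'   part of the UniProt sequence.
#' @param tagObserved whether tag residues appear in the coordinates; when
#'   `FALSE` they have no author number and are listed under REMARK 465.
#' @param insertAt 1-to-N positions receiving insertion codes
#'   (`"insertion-codes"` rule).
#' @param ligands data.frame with columns `name`, `number` of non-polymer
#'   groups, or NULL.
#' @param accession,accession2 UniProt accessions (the second one for
#'   chimeras).
#' @param chimeraSplit fraction of the chain covered by `accession` in a
#'   chimera (the remainder maps to `accession2`).
#' @param chimeraOverlap whether the two accessions' UniProt number ranges
#'   clash (TRUE: longest-coverage rule applies) or are disjoint (FALSE:
#'   both renumbered, flag "+").
#' @param mutateAt 1-to-N positions whose structure residue differs from the
#'   UniProt residue (annotated as conflicts in the SIFTS XML).
#' @param uniStart first UniProt number of the (first) mapped segment.
#' @param chainId label (PDB) chain id; `authChainId` the author chain id.
#' @param authChainId author chain id.
#' @param entryId 4-character entry id of the synthetic entry.
#' @param assemblyCopies number of chain copies in the synthetic assembly
#'   document (1 = asymmetric unit only).
#' @return a `FixtureSpec` (list) for [makeFixture()].
#' @export
fixtureSpec <- function(chainLength = 100L,
                        rule = c("identity", "constant-offset",
                                 "signal-peptide", "negative-tag",
                                 "insertion-codes", "chimera", "no-uniprot"),
                        offset = 16L, tagLength = 0L, tagObserved = TRUE,
                        insertAt = integer(), ligands = NULL,
                        accession = "P00001", accession2 = "P00002",
                        chimeraSplit = 0.8, chimeraOverlap = TRUE,
                        mutateAt = integer(), uniStart = 1L,
                        chainId = "A", authChainId = chainId,
                        entryId = "9xxx", assemblyCopies = 1L) {
    rule <- match.arg(rule)
    spec <- list(chainLength = as.integer(chainLength), rule = rule,
                 offset = as.integer(offset), tagLength = as.integer(tagLength),
                 tagObserved = isTRUE(tagObserved),
                 insertAt = as.integer(insertAt), ligands = ligands,
                 accession = accession, accession2 = accession2,
                 chimeraSplit = chimeraSplit, chimeraOverlap = chimeraOverlap,
                 mutateAt = as.integer(mutateAt), uniStart = as.integer(uniStart),
                 chainId = chainId, authChainId = authChainId,
                 entryId = entryId, assemblyCopies = as.integer(assemblyCopies))
    class(spec) <- "FixtureSpec"
    spec
}

#' Generate a coherent synthetic SIFTS + mmCIF + legacy PDB triple
#'
#' Deterministic for a given seed. Besides the three input artifacts, the
#' implied correct renumbering is emitted as an expectation table so tests
#' can check the whole pipeline against it.
#'
#' @param spec a [fixtureSpec()].
#' @param seed integer seed for the residue composition and coordinates.
#' @return list with `sifts_xml` (one string), `mmcif`
#'   ([MmcifDocument-class]), `legacy` (character lines), `expect`
#'   (data.frame: `chain`, `seq`, `auth`, `ins`, `res`, `new_mmcif`,
#'   `new_legacy`, `source`), `ligands` (with expected new numbers), and,
#'   when `assemblyCopies > 1`, `mmcif_assembly`.
#' @examples
#' fx <- makeFixture(fixtureSpec(chainLength = 6, tagLength = 2), seed = 7)
#' fx$expect
#' @export
makeFixture <- function(spec, seed = 1L) {
    stopifnot(inherits(spec, "FixtureSpec"))
    N <- spec$chainLength
    tagN <- spec$tagLength
    if (tagN >= N)
        stop("tag (", tagN, ") must be shorter than the chain (", N, ")",
             call. = FALSE)
    if (any(spec$insertAt <= 1L | spec$insertAt > N))
        stop("insertAt positions must lie in 2..chainLength", call. = FALSE)
    set.seed(seed)

    seq <- seq_len(N)
    istag <- seq <= tagN
    aa <- sample(seq_along(AA3), N, replace = TRUE)
    res <- AA3[aa]
    res[istag] <- "HIS"   # His tag
    uni1 <- AA1[aa]

    # UniProt assignment
    acc <- rep(NA_character_, N)
    uninum <- rep(NA_integer_, N)
    core <- which(!istag)
    if (spec$rule == "chimera") {
        n1 <- max(1L, round(length(core) * spec$chimeraSplit))
        seg1 <- core[seq_len(n1)]
        seg2 <- core[-seq_len(n1)]
        acc[seg1] <- spec$accession
        uninum[seg1] <- spec$uniStart + seq_along(seg1) - 1L
        acc[seg2] <- spec$accession2
        start2 <- if (spec$chimeraOverlap) spec$uniStart + 5L else
            spec$uniStart + n1 + 500L
        uninum[seg2] <- start2 + seq_along(seg2) - 1L
    } else if (spec$rule != "no-uniprot") {
        acc[core] <- spec$accession
        uninum[core] <- spec$uniStart + seq_along(core) - 1L
    }

    # author numbering
    ins <- rep("", N)
    auth <- rep(NA_integer_, N)
    base <- switch(spec$rule,
        "constant-offset" = spec$offset,
        "signal-peptide" = -spec$offset,
        0L)
    if (spec$rule == "insertion-codes") {
        cur <- spec$uniStart - tagN - 1L
        code <- 0L
        for (i in seq) {
            if (i %in% spec$insertAt) {
                code <- code + 1L
                ins[i] <- LETTERS[code]
            } else {
                cur <- cur + 1L
                code <- 0L
            }
            auth[i] <- cur
        }
    } else {
        auth[core] <- uninum[core] + base
        if (spec$rule == "chimera")  # authors number chimeras 1..N
            auth[core] <- seq_along(core) + tagN
        if (spec$rule == "no-uniprot") auth[core] <- core
        if (tagN) {
            auth[istag] <- if (spec$rule == "negative-tag")
                -(tagN:1) else auth[core][1L] - (tagN:1)
        }
    }
    if (!spec$tagObserved) auth[istag] <- NA_integer_

    # mutations: structure residue differs from UniProt residue
    mut <- seq %in% spec$mutateAt & !is.na(acc)
    uni1[mut] <- AA1[(match(uni1[mut], AA1) %% 20L) + 1L]

    truth <- data.frame(chain = spec$authChainId, pdb_chain = spec$chainId,
                        seq = seq, auth = auth, ins = ins, res = res,
                        acc = acc, uninum = uninum, uni1 = uni1,
                        mut = mut, stringsAsFactors = FALSE)

    # ---- implied correct renumbering ------------------------------------
    off <- offsetConfig()
    if (spec$rule == "no-uniprot") {
        src <- rep("none", N)
        new_mmcif <- auth
        new_legacy <- auth
    } else {
        winner <- if (spec$rule == "chimera" && spec$chimeraOverlap) {
            # longest-coverage accession wins on clash
            n1 <- sum(acc == spec$accession, na.rm = TRUE)
            n2 <- sum(acc == spec$accession2, na.rm = TRUE)
            if (n2 > n1 || (n2 == n1 && spec$accession2 < spec$accession))
                spec$accession2 else spec$accession
        } else NA_character_
        isuni <- !is.na(uninum) &
            (is.na(winner) | acc == winner)
        src <- ifelse(isuni, "uniprot", "offset")
        new_mmcif <- ifelse(isuni, uninum, off@mmcif + seq)
        new_legacy <- ifelse(isuni, uninum, off@legacy + seq)
    }
    expect <- data.frame(chain = spec$authChainId, seq = seq, auth = auth,
                         ins = ins, res = res,
                         new_mmcif = as.integer(new_mmcif),
                         new_legacy = as.integer(new_legacy),
                         source = src, stringsAsFactors = FALSE)

    ligands <- spec$ligands
    if (!is.null(ligands) && nrow(ligands)) {
        ligands$new_mmcif <- off@ligandMmcif + ligands$number
        used <- expect$new_legacy[expect$source != "none"]
        ligands$new_legacy <- reassignHeteroNumbers(used, nrow(ligands))
    }

    list(sifts_xml = fixtureSiftsXml(truth, spec),
         mmcif = fixtureMmcif(truth, spec, ligands),
         legacy = fixtureLegacy(truth, spec, ligands),
         expect = expect, ligands = ligands, spec = spec,
         mmcif_assembly = if (spec$assemblyCopies > 1L)
             fixtureAssembly(truth, spec, ligands) else NULL)
}

fixtureSiftsXml <- function(truth, spec) {
    resblocks <- vapply(seq_len(nrow(truth)), function(i) {
        r <- truth[i, ]
        authstr <- if (is.na(r$auth)) "null" else paste0(r$auth, r$ins)
        uni <- if (!is.na(r$acc)) sprintf(
            '      <crossRefDb dbSource="UniProt" dbCoordSys="UniProt" dbAccessionId="%s" dbResNum="%d" dbResName="%s"/>\n',
            r$acc, r$uninum, r$uni1) else ""
        ann <- if (!r$mut && is.na(r$auth))
            '      <residueDetail dbSource="PDBe" property="Annotation">Not_Observed</residueDetail>\n'
        else if (r$mut)
            '      <residueDetail dbSource="PDBe" property="Annotation">Conflict</residueDetail>\n'
        else ""
        sprintf(paste0(
            '    <residue dbSource="PDBe" dbCoordSys="PDBe" dbResNum="%d" dbResName="%s">\n',
            '      <crossRefDb dbSource="PDB" dbCoordSys="PDBresnum" dbAccessionId="%s" dbResNum="%s" dbResName="%s" dbChainId="%s"/>\n',
            '%s%s    </residue>'),
            r$seq, r$res, spec$entryId, authstr, r$res, r$chain, uni, ann)
    }, "")
    paste0(
        '<?xml version="1.0" encoding="UTF-8"?>\n',
        sprintf('<entry dbSource="PDBe" dbCoordSys="PDBe" dbAccessionId="%s">\n',
                spec$entryId),
        sprintf('  <entity type="protein" entityId="%s">\n', spec$chainId),
        sprintf('  <segment segId="%s_1_%d" start="1" end="%d">\n',
                spec$chainId, nrow(truth), nrow(truth)),
        "    <listResidue>\n",
        paste(resblocks, collapse = "\n"), "\n",
        "    </listResidue>\n  </segment>\n  </entity>\n</entry>\n")
}

fmtCoord <- function(x) sprintf("%.3f", x)

fixtureMmcif <- function(truth, spec, ligands, chains = NULL) {
    if (is.null(chains))
        chains <- data.frame(auth = spec$authChainId, pdb = spec$chainId,
                             stringsAsFactors = FALSE)
    obs <- truth[!is.na(truth$auth), ]
    nobs <- nrow(obs)

    atom <- list(group_PDB = character(), id = character(),
                 type_symbol = character(), label_atom_id = character(),
                 label_alt_id = character(), label_comp_id = character(),
                 label_asym_id = character(), label_entity_id = character(),
                 label_seq_id = character(), pdbx_PDB_ins_code = character(),
                 Cartn_x = character(), Cartn_y = character(),
                 Cartn_z = character(), occupancy = character(),
                 B_iso_or_equiv = character(), auth_seq_id = character(),
                 auth_comp_id = character(), auth_asym_id = character(),
                 pdbx_PDB_model_num = character())
    serial <- 0L
    for (ci in seq_len(nrow(chains))) {
        xyz <- matrix(round(stats::runif(3L * nobs, -20, 20), 3L), ncol = 3L)
        for (i in seq_len(nobs)) {
            serial <- serial + 1L
            atom <- Map(c, atom, list(
                "ATOM", as.character(serial), "C", "CA", ".", obs$res[i],
                chains$pdb[ci], "1", as.character(obs$seq[i]),
                if (nzchar(obs$ins[i])) obs$ins[i] else "?",
                fmtCoord(xyz[i, 1L]), fmtCoord(xyz[i, 2L]),
                fmtCoord(xyz[i, 3L]), "1.00", "20.00",
                as.character(obs$auth[i]), obs$res[i], chains$auth[ci], "1"))
        }
        if (!is.null(ligands) && nrow(ligands)) {
            for (l in seq_len(nrow(ligands))) {
                serial <- serial + 1L
                atom <- Map(c, atom, list(
                    "HETATM", as.character(serial), "C", "C1", ".",
                    ligands$name[l], paste0("L", ci, l), "2", ".", "?",
                    fmtCoord(stats::runif(1, -20, 20)),
                    fmtCoord(stats::runif(1, -20, 20)),
                    fmtCoord(stats::runif(1, -20, 20)), "1.00", "30.00",
                    as.character(ligands$number[l]), ligands$name[l],
                    chains$auth[ci], "1"))
            }
        }
    }

    scheme <- list(asym_id = character(), entity_id = character(),
                   seq_id = character(), mon_id = character(),
                   ndb_seq_num = character(), pdb_seq_num = character(),
                   auth_seq_num = character(), pdb_mon_id = character(),
                   auth_mon_id = character(), pdb_strand_id = character(),
                   pdb_ins_code = character())
    for (ci in seq_len(nrow(chains))) {
        for (i in seq_len(nrow(truth))) {
            r <- truth[i, ]
            o <- !is.na(r$auth)
            scheme <- Map(c, scheme, list(
                chains$pdb[ci], "1", as.character(r$seq), r$res,
                as.character(r$seq),
                if (o) as.character(r$auth) else "?",
                if (o) as.character(r$auth) else "?",
                if (o) r$res else "?", if (o) r$res else "?",
                chains$auth[ci],
                if (nzchar(r$ins)) r$ins else "."))
        }
    }

    tables <- list(
        list(category = "_entry", items = "id",
             data = list(id = spec$entryId), loop = FALSE),
        list(category = "_pdbx_poly_seq_scheme", items = names(scheme),
             data = scheme, loop = TRUE))

    if (!is.null(ligands) && nrow(ligands)) {
        np <- list(asym_id = character(), entity_id = character(),
                   mon_id = character(), ndb_seq_num = character(),
                   pdb_seq_num = character(), auth_seq_num = character(),
                   pdb_mon_id = character(), auth_mon_id = character(),
                   pdb_strand_id = character(), pdb_ins_code = character())
        for (ci in seq_len(nrow(chains)))
            for (l in seq_len(nrow(ligands)))
                np <- Map(c, np, list(
                    paste0("L", ci, l), "2", ligands$name[l], "1",
                    as.character(ligands$number[l]),
                    as.character(ligands$number[l]),
                    ligands$name[l], ligands$name[l], chains$auth[ci], "."))
        tables[[length(tables) + 1L]] <-
            list(category = "_pdbx_nonpoly_seq_scheme", items = names(np),
                 data = np, loop = TRUE)
    }

    # a helix over observed core residues exercises the annotation tables
    coreobs <- obs[obs$seq > spec$tagLength, ]
    if (nrow(coreobs) >= 5L) {
        beg <- coreobs[1L, ]
        end <- coreobs[5L, ]
        sc <- list(conf_type_id = "HELX_P", id = "H1",
                   beg_auth_comp_id = beg$res,
                   beg_auth_asym_id = chains$auth[1L],
                   beg_auth_seq_id = as.character(beg$auth),
                   pdbx_beg_PDB_ins_code = if (nzchar(beg$ins)) beg$ins else "?",
                   end_auth_comp_id = end$res,
                   end_auth_asym_id = chains$auth[1L],
                   end_auth_seq_id = as.character(end$auth),
                   pdbx_end_PDB_ins_code = if (nzchar(end$ins)) end$ins else "?")
        tables[[length(tables) + 1L]] <-
            list(category = "_struct_conf", items = names(sc),
                 data = sc, loop = FALSE)
    }

    tables[[length(tables) + 1L]] <-
        list(category = "_atom_site", items = names(atom),
             data = atom, loop = TRUE)

    new("MmcifDocument", entryId = spec$entryId, tables = tables,
        gzipped = FALSE)
}

fixtureAssembly <- function(truth, spec, ligands) {
    ids <- c(spec$authChainId,
             setdiff(LETTERS, spec$authChainId)[seq_len(spec$assemblyCopies - 1L)])
    chains <- data.frame(auth = ids,
                         pdb = paste0(spec$chainId, seq_along(ids)),
                         stringsAsFactors = FALSE)
    doc <- fixtureMmcif(truth, spec, ligands, chains = chains)
    doc@entryId <- paste0(spec$entryId, "-assembly-1")
    doc
}

fixtureLegacy <- function(truth, spec, ligands) {
    lines <- sprintf("HEADER    SYNTHETIC FIXTURE                       01-JAN-20   %s",
                     toupper(spec$entryId))
    miss <- truth[is.na(truth$auth), ]
    if (nrow(miss)) {
        lines <- c(lines,
                   "REMARK 465 MISSING RESIDUES",
                   "REMARK 465   M RES C SSSEQI")
        # depositors list unobserved tag residues with the numbers they
        # would have had; SIFTS knows them only as "null"
        fakenum <- seq_len(nrow(miss)) - nrow(miss) - 1L
        for (i in seq_len(nrow(miss)))
            lines <- c(lines, sprintf("REMARK 465     %3s %1s %5d%1s",
                                      miss$res[i], miss$chain[i],
                                      fakenum[i],
                                      if (nzchar(miss$ins[i])) miss$ins[i] else " "))
    }
    obs <- truth[!is.na(truth$auth), ]
    serial <- 0L
    set.seed(sum(utf8ToInt(spec$entryId)))
    for (i in seq_len(nrow(obs))) {
        serial <- serial + 1L
        lines <- c(lines, sprintf(
            "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            serial, obs$res[i], obs$chain[i], obs$auth[i],
            if (nzchar(obs$ins[i])) obs$ins[i] else " ",
            round(stats::runif(1, -20, 20), 3),
            round(stats::runif(1, -20, 20), 3),
            round(stats::runif(1, -20, 20), 3), 1, 20))
    }
    last <- obs[nrow(obs), ]
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d%1s",
                              serial, last$res, last$chain, last$auth,
                              if (nzchar(last$ins)) last$ins else " "))
    if (!is.null(ligands) && nrow(ligands)) {
        for (l in seq_len(nrow(ligands))) {
            serial <- serial + 1L
            lines <- c(lines, sprintf(
                "HETATM%5d  C1  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
                serial, ligands$name[l], truth$chain[1L], ligands$number[l],
                round(stats::runif(1, -20, 20), 3),
                round(stats::runif(1, -20, 20), 3),
                round(stats::runif(1, -20, 20), 3), 1, 30))
        }
    }
    c(lines, "END")
}
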