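#' Compute the target numbering for every residue
#'
#' Residues whose SIFTS row carries a UniProt number under an accession in
#' force for their chain are renumbered to that UniProt number (mutated
#' residues keep the structure's residue type together with the UniProt
#' number). Residues in UniProt-bearing chains without a UniProt number
#' (sequence tags, linkers) get `offset + seq_res_num`, with the offset
#' chosen per output format so these numbers can never collide with genuine
#' UniProt numbers. Chains with no accession are excluded from the plan and
#' left untouched by the engines.
#'
#' @param records residue table from [parseSifts()].
#' @param chainMap a [ChainAccessionMap-class] covering all chains in
#'   `records` (default: resolved on the fly).
#' @param offsets an [OffsetConfig-class].
#' @param format `"mmcif"` (offset 50000 by default) or `"legacy"`
#'   (offset 5000 by default).
#' @return A [RenumberPlan-class].
#' @examples
#' fx <- makeFixture(fixtureSpec(chainLength = 8, tagLength = 2), seed = 1)
#' rec <- parseSifts(fx$sifts_xml)
#' assignTargetNumbers(rec, resolveChainAccession(rec))
#' @export
assignTargetNumbers <- function(records,
                                chainMap = resolveChainAccession(records),
                                offsets = offsetConfig(),
                                format = c("mmcif", "legacy")) {
    format <- match.arg(format)
    off <- if (format == "mmcif") offsets@mmcif else offsets@legacy

    keep <- names(activeAccessions(chainMap))[
        lengths(activeAccessions(chainMap)) > 0L]
    r <- records[records$auth_chain_id %in% keep, , drop = FALSE]

    act <- activeAccessions(chainMap)
    isuni <- if (nrow(r) == 0L) logical(0L) else
        !is.na(r$accession) & !is.na(r$uniprot_res_num) &
        mapply(function(a, ch) a %in% act[[ch]], r$accession, r$auth_chain_id,
               USE.NAMES = FALSE)

    newnum <- ifelse(isuni, r$uniprot_res_num, off + r$seq_res_num)
    src <- ifelse(isuni, "uniprot", "offset")

    # strict range separation is required only when offset numbers are in play
    if (any(isuni) && any(!isuni) && max(r$uniprot_res_num[isuni]) >= off)
        stop(sprintf(
            paste0("UniProt residue number %d collides with the %s offset %d; ",
                   "choose a larger offset (it must exceed every UniProt number)"),
            max(r$uniprot_res_num[isuni]), format, off), call. = FALSE)

    residues <- data.frame(
        auth_chain_id = r$auth_chain_id, pdb_chain_id = r$pdb_chain_id,
        seq_res_num = r$seq_res_num, auth_res_num = r$auth_res_num,
        ins_code = r$ins_code, res_name = r$res_name,
        new_number = as.integer(newnum), source = src,
        stringsAsFactors = FALSE)

    dup <- duplicated(paste(residues$auth_chain_id, residues$new_number,
                            residues$ins_code))
    if (any(dup))
        stop(sprintf(
            "duplicate (new number, insertion code) pair %d%s in chain %s",
            residues$new_number[dup][1L], residues$ins_code[dup][1L],
            residues$auth_chain_id[dup][1L]), call. = FALSE)

    chains <- lapply(keep, function(ch) {
        ri <- residues[residues$auth_chain_id == ch, ]
        full <- records[records$auth_chain_id == ch, ]
        acc <- act[[ch]]
        sp <- chainMap@swissprot[acc]
        data.frame(
            auth_chain_id = ch, pdb_chain_id = ri$pdb_chain_id[1L],
            accession = paste(acc, collapse = ","),
            swissprot = paste(sp[!is.na(sp)], collapse = ","),
            uni_len = sum(!is.na(full$uniprot_res_num)),
            chain_len = nrow(full),
            renum = sum(ri$source == "uniprot"),
            offset_count = sum(ri$source == "offset"),
            changed = sum(is.na(ri$auth_res_num) |
                          ri$auth_res_num != ri$new_number),
            flag = chainMap@chains$flag[chainMap@chains$auth_chain_id == ch],
            stringsAsFactors = FALSE)
    })
    chains <- if (length(chains)) do.call(rbind, chains) else
        data.frame(auth_chain_id = character(), pdb_chain_id = character(),
                   accession = character(), swissprot = character(),
                   uni_len = integer(), chain_len = integer(),
                   renum = integer(), offset_count = integer(),
                   changed = integer(), flag = character(),
                   stringsAsFactors = FALSE)

    new("RenumberPlan", residues = residues, chains = chains,
        format = format, offsets = offsets)
}

#' Build the format-specific replacement lookup from a plan
#'
#' mmCIF keys are `(author number, insertion code, author chain)` tuples
#' encoded as `"num|ins|chain"`; legacy keys are the 9-character fixed-width
#' `AuthResNum(4) + InsCode(1) + ResName(3) + ChainID(1)` strings, with the
#' replacement rendered at identical width so fixed-column substitution
#' preserves line layout. Unobserved residues (no author number) are keyed by
#' `(chain, seq position)` for sequence-scheme and REMARK 465 contexts.
#'
#' Chains whose new numbers cannot be rendered in the legacy 4-character
#' residue-number field (above 9999 or below -999) are excluded from the
#' legacy map with a warning and listed in the `dropped` slot.
#'
#' @param plan a [RenumberPlan-class].
#' @param format `"mmcif"` or `"legacy"`; defaults to the plan's format.
#' @return A [ReplacementMap-class].
#' @export
buildReplacementMap <- function(plan, format = planFormat(plan)) {
    format <- match.arg(format, c("mmcif", "legacy"))
    if (format != planFormat(plan))
        stop("plan was computed for format ", sQuote(planFormat(plan)),
             "; rebuild the plan for ", sQuote(format), call. = FALSE)
    r <- planResidues(plan)

    dropped <- character()
    if (format == "legacy") {
        bad <- r$new_number > 9999L | r$new_number < -999L
        dropped <- unique(r$auth_chain_id[bad])
        if (length(dropped)) {
            warning("chain(s) ", paste(dropped, collapse = ", "),
                    " have numbers unrepresentable in legacy 4-character ",
                    "columns; excluded from legacy output", call. = FALSE)
            r <- r[!r$auth_chain_id %in% dropped, , drop = FALSE]
        }
    }

    obs <- r[!is.na(r$auth_res_num), , drop = FALSE]
    mis <- r[is.na(r$auth_res_num), , drop = FALSE]

    if (format == "mmcif") {
        auth <- stats::setNames(as.character(obs$new_number),
                                mmcifKey(obs$auth_res_num, obs$ins_code,
                                         obs$auth_chain_id))
    } else {
        auth <- stats::setNames(
            legacyKey(obs$new_number, obs$ins_code, obs$res_name,
                      obs$auth_chain_id),
            legacyKey(obs$auth_res_num, obs$ins_code, obs$res_name,
                      obs$auth_chain_id))
    }
    if (anyDuplicated(names(auth)))
        stop("replacement keys are not unique within the entry", call. = FALSE)

    seqmap <- stats::setNames(as.character(r$new_number),
                              seqKey(r$auth_chain_id, r$seq_res_num))

    missing <- data.frame(auth_chain_id = mis$auth_chain_id,
                          seq_res_num = mis$seq_res_num,
                          res_name = mis$res_name,
                          new_number = mis$new_number,
                          stringsAsFactors = FALSE)

    new("ReplacementMap", format = format, auth = auth, seq = seqmap,
        missing = missing, dropped = dropped)
}
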