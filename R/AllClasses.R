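#' @import methods
NULL

#' Offset configuration for collision-free renumbering
#'
#' Residues in UniProt-bearing chains that have no UniProt number (sequence
#' tags, linkers) are renumbered as offset + their 1-to-N position; the offset
#' differs by output format because the legacy PDB format caps residue numbers
#' at four characters (9999). Non-polymer groups in mmCIF output get their own
#' offset; in legacy output they are reassigned from the top of the available
#' 1..9999 range instead (see [reassignHeteroNumbers()]).
#'
#' @slot mmcif integer offset for tag residues in mmCIF output (default 50000).
#' @slot legacy integer offset for tag residues in legacy PDB output
#'   (default 5000).
#' @slot ligandMmcif integer offset added to non-polymer residue numbers in
#'   mmCIF output (default 60000).
#' @slot legacyCap largest residue number representable in the legacy
#'   fixed-column format (9999).
#' @export
setClass("OffsetConfig",
    representation(mmcif = "integer", legacy = "integer",
                   ligandMmcif = "integer", legacyCap = "integer"),
    prototype(mmcif = 50000L, legacy = 5000L,
              ligandMmcif = 60000L, legacyCap = 9999L))

setValidity("OffsetConfig", function(object) {
    v <- c(object@mmcif, object@legacy, object@ligandMmcif, object@legacyCap)
    if (length(v) != 4L || anyNA(v)) return("all offsets must be single non-NA integers")
    if (any(v <= 0L)) return("all offsets must be positive")
    TRUE
})

#' Construct an OffsetConfig
#'
#' @param mmcif,legacy,ligandMmcif,legacyCap see [OffsetConfig-class].
#' @return An [OffsetConfig-class] object.
#' @examples
#' offsetConfig()
#' offsetConfig(mmcif = 70000)
#' @export
offsetConfig <- function(mmcif = 50000L, legacy = 5000L,
                         ligandMmcif = 60000L, legacyCap = 9999L) {
    new("OffsetConfig", mmcif = as.integer(mmcif), legacy = as.integer(legacy),
        ligandMmcif = as.integer(ligandMmcif), legacyCap = as.integer(legacyCap))
}

#' Per-chain accession resolution
#'
#' For each author chain, which UniProt accession(s) drive its renumbering.
#' Chains mapping to a single accession carry a blank flag; chimeric chains
#' whose accessions occupy non-overlapping UniProt number ranges keep all of
#' them (flag "+"); chains with clashing ranges keep the accession covering
#' the most residues (flag "*"), skipping accessions on the crystallization
#' chaperone exception list.
#'
#' @slot chains data.frame with one row per author chain: `auth_chain_id`,
#'   `pdb_chain_id`, `flag` ("", "+", "*"), `accession` (active accessions,
#'   comma-separated; "" when none), `n_candidates`.
#' @slot active named list: auth chain id -> character vector of active
#'   accessions (may be empty).
#' @slot coverage named list: auth chain id -> named integer vector of residue
#'   counts per candidate accession.
#' @slot swissprot named character: accession -> SwissProt-style ID where known.
#' @export
setClass("ChainAccessionMap",
    representation(chains = "data.frame", active = "list",
                   coverage = "list", swissprot = "character"))

setValidity("ChainAccessionMap", function(object) {
    ch <- object@chains
    need <- c("auth_chain_id", "pdb_chain_id", "flag", "accession", "n_candidates")
    if (!all(need %in% names(ch))) return("chains slot missing required columns")
    if (!all(ch$flag %in% c("", "+", "*"))) return("flag must be one of '', '+', '*'")
    if (!setequal(names(object@active), ch$auth_chain_id))
        return("active list must cover exactly the chains")
    none <- lengths(object@active)[ch$auth_chain_id] == 0L
    if (any(none & ch$n_candidates > 0L))
        return("chains with candidate accessions must keep at least one")
    TRUE
})

#' Target numbering plan for one entry
#'
#' The computed replacement numbering for every residue of every
#' UniProt-bearing chain, together with per-chain summary counts.
#'
#' @slot residues data.frame: `auth_chain_id`, `pdb_chain_id`, `seq_res_num`,
#'   `auth_res_num` (NA when unobserved), `ins_code`, `res_name`,
#'   `new_number`, `source` ("uniprot" or "offset").
#' @slot chains data.frame: per-chain `accession`, `swissprot`, `uni_len`,
#'   `chain_len`, `renum`, `offset_count`, `changed`, `flag`.
#' @slot format "mmcif" or "legacy".
#' @slot offsets the [OffsetConfig-class] used.
#' @export
setClass("RenumberPlan",
    representation(residues = "data.frame", chains = "data.frame",
                   format = "character", offsets = "OffsetConfig"))

setValidity("RenumberPlan", function(object) {
    r <- object@residues
    if (!object@format %in% c("mmcif", "legacy"))
        return("format must be 'mmcif' or 'legacy'")
    if (nrow(r) == 0L) return(TRUE)
    key <- paste(r$auth_chain_id, r$new_number, r$ins_code)
    if (anyDuplicated(key))
        return("(new_number, ins_code) pairs must be unique within a chain")
    uni <- r$new_number[r$source == "uniprot"]
    off <- r$new_number[r$source == "offset"]
    if (length(uni) && length(off) && max(uni) >= min(off))
        return("offset-derived numbers must all exceed UniProt-derived numbers")
    TRUE
})

#' Format-specific residue replacement lookup
#'
#' Maps a residue's original identity to its new number. mmCIF keys are
#' `"<auth number>|<ins code>|<auth chain>"`; legacy keys are the 9-character
#' fixed-width string `AuthResNum(4) + InsCode(1) + ResName(3) + ChainID(1)`
#' with the replacement rendered at identical width. Residues with no author
#' number (unobserved) are keyed by `"<chain>|<seq position>"` in the `seq`
#' slot for sequence-scheme and REMARK 465 contexts.
#'
#' @slot format "mmcif" or "legacy".
#' @slot auth named character: format-specific key -> replacement.
#' @slot seq named character: `"<chain>|<seq>"` -> new number (as string).
#' @slot missing data.frame of unobserved residues (`auth_chain_id`,
#'   `seq_res_num`, `res_name`, `new_number`) used for ordered REMARK 465
#'   matching in the legacy engine.
#' @slot dropped character: chains excluded because their numbers cannot be
#'   rendered in the legacy fixed-width columns.
#' @export
setClass("ReplacementMap",
    representation(format = "character", auth = "character", seq = "character",
                   missing = "data.frame", dropped = "character"))

setValidity("ReplacementMap", function(object) {
    if (!object@format %in% c("mmcif", "legacy"))
        return("format must be 'mmcif' or 'legacy'")
    if (object@format == "legacy" && length(object@auth)) {
        if (any(nchar(names(object@auth)) != 9L) || any(nchar(object@auth) != 9L))
            return("legacy keys and values must be exactly 9 characters")
    }
    TRUE
})

#' An mmCIF document as an ordered set of string tables
#'
#' Both loop and key-value categories are held as tables of named character
#' columns, in file order; content the renumbering engine does not touch is
#' carried through value-faithfully, so read -> write round-trips preserve
#' every value.
#'
#' @slot entryId the data block name (usually the PDB id).
#' @slot tables list; each element has `category` (e.g. "_atom_site"),
#'   `items` (character), `data` (named list of character vectors), `loop`
#'   (logical).
#' @slot gzipped whether the source stream was gzip-compressed.
#' @export
setClass("MmcifDocument",
    representation(entryId = "character", tables = "list", gzipped = "logical"),
    prototype(entryId = "", tables = list(), gzipped = FALSE))

setValidity("MmcifDocument", function(object) {
    for (tb in object@tables) {
        if (!all(c("category", "items", "data", "loop") %in% names(tb)))
            return("each table needs category, items, data, loop")
        if (!identical(tb$items, names(tb$data)))
            return("table items and data names must agree")
        n <- unique(lengths(tb$data))
        if (length(n) > 1L)
            return(sprintf("ragged columns in %s", tb$category))
    }
    TRUE
})

setMethod("show", "OffsetConfig", function(object) {
    cat(sprintf(
        "OffsetConfig: mmCIF tag +%d, legacy tag +%d, mmCIF ligand +%d, legacy cap %d\n",
        object@mmcif, object@legacy, object@ligandMmcif, object@legacyCap))
})

setMethod("show", "ChainAccessionMap", function(object) {
    cat(sprintf("ChainAccessionMap for %d chain(s)\n", nrow(object@chains)))
    print(object@chains, row.names = FALSE)
})

setMethod("show", "RenumberPlan", function(object) {
    cat(sprintf("RenumberPlan (%s): %d residue(s) across %d chain(s)\n",
                object@format, nrow(object@residues), nrow(object@chains)))
    if (nrow(object@chains))
        print(object@chains[, c("auth_chain_id", "accession", "uni_len",
                                "chain_len", "renum", "offset_count", "flag")],
              row.names = FALSE)
})

setMethod("show", "ReplacementMap", function(object) {
    cat(sprintf("ReplacementMap (%s): %d keyed residue(s), %d unobserved, %d chain(s) dropped\n",
                object@format, length(object@auth), nrow(object@missing),
                length(object@dropped)))
})

setMethod("show", "MmcifDocument", function(object) {
    cat(sprintf("MmcifDocument '%s': %d table(s)\n",
                object@entryId, length(object@tables)))
    for (tb in object@tables)
        cat(sprintf("  %s [%d x %d]\n", tb$category,
                    if (length(tb$data)) length(tb$data[[1L]]) else 0L,
                    length(tb$items)))
})

#' Accessors for plan and map objects
#'
#' @param x a [RenumberPlan-class], [ChainAccessionMap-class] or
#'   [MmcifDocument-class].
#' @return `planResidues`/`planChains` return the corresponding data.frame;
#'   `planFormat` the format string; `chainFlags` a named character vector of
#'   special-case flags; `activeAccessions` the named list of accessions in
#'   force per chain.
#' @name plan-accessors
NULL

#' @rdname plan-accessors
#' @export
planResidues <- function(x) x@residues

#' @rdname plan-accessors
#' @export
planChains <- function(x) x@chains

#' @rdname plan-accessors
#' @export
planFormat <- function(x) x@format

#' @rdname plan-accessors
#' @export
chainFlags <- function(x) stats::setNames(x@chains$flag, x@chains$auth_chain_id)

#' @rdname plan-accessors
#' @export
activeAccessions <- function(x) x@active
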