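`%||%` <- function(a, b) if (is.null(a)) b else a

# mmCIF null/inapplicable markers and blanks all denote "no insertion code"
normalizeIns <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x %in% c("?", ".", " ", "")] <- ""
    x
}

# strict integer parse; NA for anything else (keeps "." / "?" / text out)
parseIntStrict <- function(x) {
    x <- trimws(as.character(x))
    ok <- grepl("^-?[0-9]+$", x)
    out <- rep(NA_integer_, length(x))
    out[ok] <- as.integer(x[ok])
    out
}

mmcifKey <- function(num, ins, chain) {
    paste(trimws(as.character(num)), normalizeIns(ins), as.character(chain),
          sep = "|")
}

seqKey <- function(chain, seq) paste(chain, seq, sep = "|")

# AuthResNum(4) + InsCode(1) + ResName(3) + ChainID(1), fixed width
legacyKey <- function(num, ins, res, chain) {
    ins <- normalizeIns(ins)
    ins[ins == ""] <- " "
    sprintf("%4s%1s%3s%1s", as.character(num), ins,
            as.character(res), as.character(chain))
}

emptyResidueRecords <- function() {
    data.frame(pdb_chain_id = character(), auth_chain_id = character(),
               seq_res_num = integer(), auth_res_num = integer(),
               ins_code = character(), res_name = character(),
               accession = character(), uniprot_res_num = integer(),
               uniprot_res_name = character(), is_mutation = logical(),
               stringsAsFactors = FALSE)
}
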