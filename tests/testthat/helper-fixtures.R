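# shared test helpers: plan construction from fixtures, an independent
# brute-force accession resolver, and a fixture-backed input directory layout

planFromFixture <- function(fx, format = "mmcif", offsets = offsetConfig(),
                            exceptions = chaperoneExceptions(),
                            uniprotNames = character()) {
    rec <- parseSifts(fx$sifts_xml)
    assignTargetNumbers(rec, resolveChainAccession(rec, exceptions,
                                                   uniprotNames),
                        offsets, format)
}

# literal restatement of the resolution rule, written independently of the
# implementation: overlap decided on shared integers, winner by explicit
# coverage scan over all candidates
bruteResolveChain <- function(records, chain, exceptions = character(),
                              uniprotNames = character()) {
    sub <- records[records$auth_chain_id == chain & !is.na(records$accession), ]
    accs <- sort(unique(sub$accession))
    if (length(accs) == 0L) return(list(active = character(), flag = ""))
    if (length(accs) == 1L) return(list(active = accs, flag = ""))
    numsets <- lapply(accs, function(a) {
        r <- range(sub$uniprot_res_num[sub$accession == a])
        seq(r[1L], r[2L])
    })
    clash <- FALSE
    for (a in seq_along(accs))
        for (b in seq_along(accs))
            if (a != b && length(intersect(numsets[[a]], numsets[[b]])))
                clash <- TRUE
    if (!clash) return(list(active = accs, flag = "+"))
    cov <- vapply(accs, function(a) sum(sub$accession == a), integer(1L))
    isexc <- vapply(accs, function(a) {
        a %in% exceptions ||
            (!is.na(uniprotNames[a]) && uniprotNames[a] %in% exceptions)
    }, logical(1L))
    best <- function(pool) {
        if (!length(pool)) return(character())
        mx <- max(cov[match(pool, accs)])
        sort(pool[cov[match(pool, accs)] == mx])[1L]
    }
    pick <- best(accs[!isexc])
    if (!length(pick)) pick <- best(accs)
    list(active = pick, flag = "*")
}

# drop fixture inputs into a defaultPaths()-shaped directory tree
writeFixtureInputs <- function(fx, base, id = fx$spec$entryId,
                               kinds = c("mmCIF", "PDB")) {
    p <- defaultPaths(base)
    for (k in c(kinds, "SIFTS"))
        dir.create(p[[k]], showWarnings = FALSE, recursive = TRUE)
    if ("mmCIF" %in% kinds)
        writeMmcif(fx$mmcif, file.path(p$mmCIF, paste0(id, ".cif.gz")))
    if ("PDB" %in% kinds)
        writeLegacy(fx$legacy, file.path(p$PDB, paste0(id, ".pdb.gz")))
    con <- gzfile(file.path(p$SIFTS, paste0(id, ".xml.gz")), "wt")
    writeLines(fx$sifts_xml, con)
    close(con)
    p
}

# the standard battery of numbering pathologies exercised by property tests
fixtureBattery <- function() {
    list(
        identity = fixtureSpec(chainLength = 20, rule = "identity"),
        offset = fixtureSpec(chainLength = 25, rule = "constant-offset",
                             offset = 16, tagLength = 3),
        signal = fixtureSpec(chainLength = 30, rule = "signal-peptide",
                             offset = 30, uniStart = 31),
        negtag = fixtureSpec(chainLength = 18, rule = "negative-tag",
                             tagLength = 4),
        unobs = fixtureSpec(chainLength = 15, rule = "identity",
                            tagLength = 3, tagObserved = FALSE),
        inscode = fixtureSpec(chainLength = 22, rule = "insertion-codes",
                              insertAt = c(8, 15), uniStart = 5),
        chimera = fixtureSpec(chainLength = 40, rule = "chimera",
                              chimeraSplit = 0.8),
        chimplus = fixtureSpec(chainLength = 40, rule = "chimera",
                               chimeraOverlap = FALSE),
        ligand = fixtureSpec(chainLength = 20, tagLength = 2,
                             ligands = data.frame(name = c("ZN", "MG"),
                                                  number = c(1, 2)))
    )
}
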