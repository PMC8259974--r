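# SIFTS parsing and per-chain accession resolution

test_that("parseSifts links 1-to-N, author and UniProt numbering per residue", {
    fx <- makeFixture(fixtureSpec(chainLength = 5, tagLength = 2), seed = 1)
    rec <- parseSifts(fx$sifts_xml)
    expect_equal(nrow(rec), 5L)
    expect_equal(rec$seq_res_num, 1:5)
    # hand-enumerated: exactly the 3 non-tag residues carry an accession
    expect_equal(sum(!is.na(rec$accession)), 3L)
    expect_true(all(is.na(rec$accession) == is.na(rec$uniprot_res_num)))
})

test_that("unobserved expression tags have absent author numbers and no accession", {
    # emulates an N-terminal His tag absent from the coordinates
    fx <- makeFixture(fixtureSpec(chainLength = 10, tagLength = 3,
                                  tagObserved = FALSE), seed = 2)
    rec <- parseSifts(fx$sifts_xml)
    tag <- rec[rec$seq_res_num <= 3, ]
    expect_true(all(is.na(tag$auth_res_num)))
    expect_true(all(is.na(tag$accession)))
    expect_true(all(tag$res_name == "HIS"))
    # observed residues all carry author numbers
    expect_true(all(!is.na(rec$auth_res_num[rec$seq_res_num > 3])))
})

test_that("author numbers with trailing letters split into number + insertion code", {
    fx <- makeFixture(fixtureSpec(chainLength = 12, rule = "insertion-codes",
                                  insertAt = c(5, 9)), seed = 3)
    rec <- parseSifts(fx$sifts_xml)
    expect_equal(rec$ins_code[5], "A")
    expect_equal(rec$ins_code[9], "A")
    expect_equal(rec$auth_res_num[5], rec$auth_res_num[4])
    expect_true(all(rec$ins_code[-c(5, 9)] == ""))
    expect_true(all(grepl("^$|^[A-Z]$", rec$ins_code)))
})

test_that("negative author numbers parse as signed integers", {
    fx <- makeFixture(fixtureSpec(chainLength = 10, rule = "negative-tag",
                                  tagLength = 3), seed = 4)
    rec <- parseSifts(fx$sifts_xml)
    expect_equal(rec$auth_res_num[1:3], c(-3L, -2L, -1L))
})

test_that("a document with zero protein chains yields an empty table", {
    xml <- paste0('<?xml version="1.0"?><entry dbAccessionId="9zzz">',
                  '<entity type="ligand" entityId="B"/></entry>')
    rec <- parseSifts(xml)
    expect_equal(nrow(rec), 0L)
    expect_named(rec, c("pdb_chain_id", "auth_chain_id", "seq_res_num",
                        "auth_res_num", "ins_code", "res_name", "accession",
                        "uniprot_res_num", "uniprot_res_name", "is_mutation"))
})

test_that("malformed XML and non-integer author cores are reported", {
    expect_error(parseSifts("<entry><entity>"), "malformed")
    xml <- paste0(
        '<?xml version="1.0"?><entry dbAccessionId="9bad">',
        '<entity type="protein" entityId="A"><segment><listResidue>',
        '<residue dbSource="PDBe" dbResNum="1" dbResName="ALA">',
        '<crossRefDb dbSource="PDB" dbResNum="12abc" dbResName="ALA" dbChainId="A"/>',
        '</residue></listResidue></segment></entity></entry>')
    expect_error(parseSifts(xml), "non-integer author")
    expect_error(parseSifts(xml), "chain A")
})

test_that("mutation annotations are carried on the residue records", {
    fx <- makeFixture(fixtureSpec(chainLength = 10, mutateAt = 4), seed = 5)
    rec <- parseSifts(fx$sifts_xml)
    expect_true(rec$is_mutation[4])
    expect_equal(sum(rec$is_mutation), 1L)
})

test_that("single-accession chains resolve without a flag", {
    fx <- makeFixture(fixtureSpec(chainLength = 10), seed = 1)
    cm <- resolveChainAccession(parseSifts(fx$sifts_xml))
    expect_equal(cm@chains$flag, "")
    expect_equal(cm@chains$accession, "P00001")
})

test_that("clashing chimeras keep the largest-coverage accession, flag '*'", {
    # 80/20 split with overlapping UniProt ranges
    fx <- makeFixture(fixtureSpec(chainLength = 160, rule = "chimera",
                                  chimeraSplit = 0.75), seed = 6)
    rec <- parseSifts(fx$sifts_xml)
    cm <- resolveChainAccession(rec)
    expect_equal(cm@chains$flag, "*")
    expect_equal(activeAccessions(cm)$A, "P00001")
})

test_that("non-overlapping chimeras keep all accessions, flag '+'", {
    fx <- makeFixture(fixtureSpec(chainLength = 60, rule = "chimera",
                                  chimeraOverlap = FALSE), seed = 7)
    cm <- resolveChainAccession(parseSifts(fx$sifts_xml))
    expect_equal(cm@chains$flag, "+")
    expect_setequal(activeAccessions(cm)$A, c("P00001", "P00002"))
})

test_that("chaperone exceptions lose the clash even when longer", {
    fx <- makeFixture(fixtureSpec(chainLength = 50, rule = "chimera",
                                  chimeraSplit = 0.8,
                                  accession = "P42212",   # covers 80%
                                  accession2 = "P99999"), seed = 8)
    rec <- parseSifts(fx$sifts_xml)
    nm <- c(P42212 = "GFP_AEQVI")
    cm <- resolveChainAccession(rec, uniprotNames = nm)
    expect_equal(activeAccessions(cm)$A, "P99999")
    expect_equal(cm@chains$flag, "*")
    # exhaustive check of the stated rule on this 2-candidate fixture
    oracle <- bruteResolveChain(rec, "A", chaperoneExceptions(), nm)
    expect_equal(activeAccessions(cm)$A, oracle$active)
    # accession-form exceptions match too
    cm2 <- resolveChainAccession(rec, exceptions = "P42212")
    expect_equal(activeAccessions(cm2)$A, "P99999")
})

test_that("resolution agrees with a brute-force restatement of the rule", {
    specs <- list(
        fixtureSpec(chainLength = 30, rule = "chimera", chimeraSplit = 0.6),
        fixtureSpec(chainLength = 45, rule = "chimera", chimeraSplit = 0.5),
        fixtureSpec(chainLength = 50, rule = "chimera", chimeraOverlap = FALSE),
        fixtureSpec(chainLength = 40, rule = "identity"),
        fixtureSpec(chainLength = 20, rule = "no-uniprot"))
    for (s in seq_along(specs)) {
        rec <- parseSifts(makeFixture(specs[[s]], seed = 100 + s)$sifts_xml)
        cm <- resolveChainAccession(rec)
        for (ch in unique(rec$auth_chain_id)) {
            oracle <- bruteResolveChain(rec, ch)
            expect_equal(sort(activeAccessions(cm)[[ch]]),
                         sort(oracle$active),
                         info = sprintf("spec %d chain %s", s, ch))
            expect_equal(chainFlags(cm)[[ch]], oracle$flag,
                         info = sprintf("spec %d chain %s", s, ch))
        }
    }
})

test_that("chains without UniProt rows keep no accession", {
    fx <- makeFixture(fixtureSpec(chainLength = 12, rule = "no-uniprot"),
                      seed = 9)
    cm <- resolveChainAccession(parseSifts(fx$sifts_xml))
    expect_length(activeAccessions(cm)$A, 0L)
    expect_equal(cm@chains$flag, "")
})
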