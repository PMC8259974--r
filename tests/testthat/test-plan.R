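# Target-number assignment and replacement-map construction

test_that("UniProt numbers replace shifted author numbers", {
    # author numbering = UniProt + 16, so author 18 must become 2
    fx <- makeFixture(fixtureSpec(chainLength = 10, rule = "constant-offset",
                                  offset = 16, uniStart = 1), seed = 1)
    plan <- planFromFixture(fx)
    r <- planResidues(plan)
    expect_equal(r$new_number[r$auth_res_num == 18], 2L)
    expect_equal(r$source[r$auth_res_num == 18], "uniprot")
})

test_that("tag residues get offset + 1-to-N position, per format", {
    fx <- makeFixture(fixtureSpec(chainLength = 10, tagLength = 2), seed = 2)
    pm <- planFromFixture(fx, "mmcif")
    pl <- planFromFixture(fx, "legacy")
    expect_equal(planResidues(pm)$new_number[1:2], c(50001L, 50002L))
    expect_equal(planResidues(pl)$new_number[1:2], c(5001L, 5002L))
    expect_equal(planResidues(pm)$source[1:2], rep("offset", 2L))
})

test_that("already-UniProt-numbered chains map every number to itself", {
    fx <- makeFixture(fixtureSpec(chainLength = 20, rule = "identity"),
                      seed = 3)
    plan <- planFromFixture(fx)
    r <- planResidues(plan)
    expect_equal(r$new_number, r$auth_res_num)
})

test_that("mutated residues keep the structure residue type with the UniProt number", {
    fx <- makeFixture(fixtureSpec(chainLength = 10, rule = "constant-offset",
                                  offset = 5, mutateAt = 4), seed = 4)
    rec <- parseSifts(fx$sifts_xml)
    plan <- assignTargetNumbers(rec, resolveChainAccession(rec))
    r <- planResidues(plan)
    expect_equal(r$res_name[4], rec$res_name[4])        # structure type kept
    expect_equal(r$new_number[4], rec$uniprot_res_num[4])
    expect_equal(r$source[4], "uniprot")
})

test_that("chains with no accession are excluded from the plan", {
    fx <- makeFixture(fixtureSpec(chainLength = 10, rule = "no-uniprot"),
                      seed = 5)
    plan <- planFromFixture(fx)
    expect_equal(nrow(planResidues(plan)), 0L)
    expect_equal(nrow(planChains(plan)), 0L)
})

test_that("a UniProt number at or above the offset raises a collision error", {
    fx <- makeFixture(fixtureSpec(chainLength = 10, uniStart = 49995,
                                  tagLength = 1), seed = 6)
    rec <- parseSifts(fx$sifts_xml)
    cm <- resolveChainAccession(rec)
    expect_error(assignTargetNumbers(rec, cm, format = "mmcif"),
                 "larger offset")
    # a larger offset resolves it
    expect_s4_class(assignTargetNumbers(rec, cm, offsetConfig(mmcif = 60000),
                                        format = "mmcif"),
                    "RenumberPlan")
})

test_that("per-chain counts summarise renumbered and offset residues", {
    fx <- makeFixture(fixtureSpec(chainLength = 15, tagLength = 3), seed = 7)
    plan <- planFromFixture(fx)
    ch <- planChains(plan)
    expect_equal(ch$chain_len, 15L)
    expect_equal(ch$uni_len, 12L)
    expect_equal(ch$renum, 12L)
    expect_equal(ch$offset_count, 3L)
    expect_true(ch$renum + ch$offset_count <= ch$chain_len)
})

test_that("plans are injective per chain with offset numbers above UniProt numbers", {
    battery <- fixtureBattery()
    for (nm in names(battery)) {
        fx <- makeFixture(battery[[nm]], seed = match(nm, names(battery)))
        for (fmt in c("mmcif", "legacy")) {
            plan <- planFromFixture(fx, fmt)
            r <- planResidues(plan)
            if (!nrow(r)) next
            for (ch in unique(r$auth_chain_id)) {
                ri <- r[r$auth_chain_id == ch, ]
                expect_false(anyDuplicated(paste(ri$new_number, ri$ins_code)) > 0,
                             label = sprintf("%s/%s injective", nm, fmt))
            }
            uni <- r$new_number[r$source == "uniprot"]
            off <- r$new_number[r$source == "offset"]
            if (length(uni) && length(off))
                expect_lt(max(uni), min(off),
                          label = sprintf("%s/%s range separation", nm, fmt))
        }
    }
})

test_that("legacy keys are fixed 9-character strings with value at same width", {
    fx <- makeFixture(fixtureSpec(chainLength = 5, rule = "identity",
                                  uniStart = 98), seed = 8)
    plan <- planFromFixture(fx, "legacy")
    map <- buildReplacementMap(plan)
    expect_true(all(nchar(names(map@auth)) == 9L))
    expect_true(all(nchar(map@auth) == 9L))
    # residue 100, no ins code, chain A: " 100 XXXA" layout (4+1+3+1)
    r <- planResidues(plan)
    k <- names(map@auth)[r$auth_res_num == 100]
    expect_equal(substr(k, 1, 4), " 100")
    expect_equal(substr(k, 5, 5), " ")
    expect_equal(substr(k, 9, 9), "A")
})

test_that("insertion codes sit at position 5 of the legacy key", {
    fx <- makeFixture(fixtureSpec(chainLength = 12, rule = "insertion-codes",
                                  insertAt = 6, uniStart = 96), seed = 9)
    plan <- planFromFixture(fx, "legacy")
    map <- buildReplacementMap(plan)
    k <- names(map@auth)[planResidues(plan)$ins_code == "A"]
    expect_equal(substr(k, 5, 5), "A")
    # ins code carried through into the replacement value
    expect_equal(unname(substr(map@auth[k], 5, 5)), "A")
})

test_that("an empty plan yields an empty map", {
    fx <- makeFixture(fixtureSpec(chainLength = 6, rule = "no-uniprot"),
                      seed = 10)
    map <- buildReplacementMap(planFromFixture(fx))
    expect_length(map@auth, 0L)
})

test_that("unobserved residues are keyed by chain and sequence position", {
    fx <- makeFixture(fixtureSpec(chainLength = 8, tagLength = 2,
                                  tagObserved = FALSE), seed = 11)
    map <- buildReplacementMap(planFromFixture(fx))
    expect_equal(unname(map@seq[c("A|1", "A|2")]),
                 c("50001", "50002"))
    expect_equal(nrow(map@missing), 2L)
})

test_that("chains unrepresentable in legacy columns are dropped with a warning", {
    # UniProt numbers beyond 9999 cannot fit the 4-character field
    fx <- makeFixture(fixtureSpec(chainLength = 10, uniStart = 9995),
                      seed = 12)
    plan <- planFromFixture(fx, "legacy")
    expect_warning(map <- buildReplacementMap(plan), "unrepresentable")
    expect_equal(map@dropped, "A")
    expect_length(map@auth, 0L)
})

test_that("mmCIF and legacy plans agree on every UniProt-numbered residue", {
    battery <- fixtureBattery()
    for (nm in names(battery)) {
        fx <- makeFixture(battery[[nm]], seed = 20 + match(nm, names(battery)))
        rm <- planResidues(planFromFixture(fx, "mmcif"))
        rl <- planResidues(planFromFixture(fx, "legacy"))
        um <- rm[rm$source == "uniprot", c("auth_chain_id", "seq_res_num",
                                           "new_number")]
        ul <- rl[rl$source == "uniprot", c("auth_chain_id", "seq_res_num",
                                           "new_number")]
        expect_equal(um, ul, label = nm)
    }
})
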