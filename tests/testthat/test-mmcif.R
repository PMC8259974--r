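# mmCIF reading, writing, item enumeration, renumbering, scheme rewrite

test_that("a minimal key-value file parses to one table with one row", {
    doc <- readMmcif(c("data_test", "_entry.id   test"), isLines = TRUE)
    expect_equal(cifCategories(doc), "_entry")
    expect_equal(cifTable(doc, "_entry")$id, "test")
    expect_equal(doc@entryId, "test")
})

test_that("loop values, quoting and text fields round-trip value-faithfully", {
    lines <- c("data_q",
               "_note.text    'a value with spaces'",
               "loop_", "_t.a", "_t.b",
               "x 'y z'", "? .", "\"it's\" w",
               "_long.text", ";first", "second", ";")
    doc <- readMmcif(lines, isLines = TRUE)
    expect_equal(cifTable(doc, "_t")$a, c("x", "?", "it's"))
    expect_equal(cifTable(doc, "_t")$b, c("y z", ".", "w"))
    expect_equal(cifTable(doc, "_long")$text, "first\nsecond")
    tf <- withr::local_tempfile(fileext = ".cif")
    writeMmcif(doc, tf, gzip = FALSE)
    doc2 <- readMmcif(tf)
    expect_identical(lapply(doc@tables, `[[`, "data"),
                     lapply(doc2@tables, `[[`, "data"))
})

test_that("documents round-trip through write and read, gzipped or not", {
    fx <- makeFixture(fixtureSpec(chainLength = 20, tagLength = 2,
                                  ligands = data.frame(name = "ZN",
                                                       number = 1)),
                      seed = 1)
    tgz <- withr::local_tempfile(fileext = ".cif.gz")
    tpl <- withr::local_tempfile(fileext = ".cif")
    writeMmcif(fx$mmcif, tgz, gzip = TRUE)
    writeMmcif(fx$mmcif, tpl, gzip = FALSE)
    dgz <- readMmcif(tgz)
    dpl <- readMmcif(tpl)
    expect_identical(lapply(dgz@tables, `[[`, "data"),
                     lapply(dpl@tables, `[[`, "data"))
    expect_identical(lapply(dgz@tables, `[[`, "data"),
                     lapply(fx$mmcif@tables, `[[`, "data"))
    expect_true(dgz@gzipped)
})

test_that("syntax errors are reported with a line number", {
    expect_error(readMmcif(c("data_x", "loop_", "_t.a", "_t.b", "1"),
                           isLines = TRUE), "line")
    expect_error(readMmcif(c("data_x", "_t.a"), isLines = TRUE), "no value")
})

test_that("item enumeration intersects the static list with present tables", {
    fx <- makeFixture(fixtureSpec(chainLength = 10), seed = 2)
    items <- enumerateRenumberableItems(fx$mmcif)
    expect_true("_atom_site" %in% items$category)
    asrow <- items[items$category == "_atom_site", ]
    expect_equal(asrow$number_item, "auth_seq_id")
    expect_equal(asrow$chain_item, "auth_asym_id")
    expect_equal(asrow$ins_item, "pdbx_PDB_ins_code")
    # beg/end pair in _struct_conf both found with their own companions
    sc <- items[items$category == "_struct_conf", ]
    expect_setequal(sc$number_item, c("beg_auth_seq_id", "end_auth_seq_id"))
    expect_setequal(sc$chain_item, c("beg_auth_asym_id", "end_auth_asym_id"))
    expect_setequal(sc$ins_item, c("pdbx_beg_PDB_ins_code",
                                   "pdbx_end_PDB_ins_code"))
})

test_that("documents without residue-numbered tables enumerate nothing", {
    doc <- readMmcif(c("data_z", "_entry.id z", "_cell.length_a 10.0"),
                     isLines = TRUE)
    expect_equal(nrow(enumerateRenumberableItems(doc)), 0L)
})

test_that("renumbering rewrites number columns and nothing else", {
    fx <- makeFixture(fixtureSpec(chainLength = 12, tagLength = 2,
                                  ligands = data.frame(name = "ZN",
                                                       number = 5)),
                      seed = 3)
    plan <- planFromFixture(fx)
    before <- cifTable(fx$mmcif, "_atom_site")
    doc <- renumberMmcif(fx$mmcif, plan)
    after <- cifTable(doc, "_atom_site")
    untouched <- setdiff(names(before), "auth_seq_id")
    expect_identical(after[untouched], before[untouched])
    expect_false(identical(after$auth_seq_id, before$auth_seq_id))
    # row counts conserved in every pre-existing table
    for (cat in cifCategories(fx$mmcif))
        expect_equal(nrow(cifTable(doc, cat)),
                     nrow(cifTable(fx$mmcif, cat)), label = cat)
})

test_that("ligand rows get the non-polymer offset", {
    fx <- makeFixture(fixtureSpec(chainLength = 10,
                                  ligands = data.frame(name = "ZN",
                                                       number = 5)),
                      seed = 4)
    doc <- renumberMmcif(fx$mmcif, planFromFixture(fx))
    as_ <- cifTable(doc, "_atom_site")
    expect_equal(as_$auth_seq_id[as_$group_PDB == "HETATM"], "60005")
    np <- cifTable(doc, "_pdbx_nonpoly_seq_scheme")
    expect_equal(np$pdb_seq_num, "60005")
    expect_equal(np$auth_seq_num, "5")
})

test_that("the engine agrees with per-row brute-force substitution", {
    battery <- fixtureBattery()
    for (nm in names(battery)) {
        fx <- makeFixture(battery[[nm]], seed = 40 + match(nm, names(battery)))
        plan <- planFromFixture(fx)
        if (!nrow(planResidues(plan))) next
        doc <- renumberMmcif(fx$mmcif, plan)
        r <- planResidues(plan)
        items <- enumerateRenumberableItems(fx$mmcif)
        for (k in seq_len(nrow(items))) {
            it <- items[k, ]
            if (it$role %in% c("scheme", "nonpoly-scheme")) next
            tin <- cifTable(fx$mmcif, it$category)
            tout <- cifTable(doc, it$category)
            for (row in seq_len(nrow(tin))) {
                if (it$category == "_atom_site" &&
                    (tin$group_PDB[row] == "HETATM" ||
                     tin$label_seq_id[row] %in% c(".", "?"))) {
                    # non-polymer rows take the ligand offset
                    expect_equal(tout[[it$number_item]][row],
                                 as.character(60000L +
                                     as.integer(tin[[it$number_item]][row])),
                                 label = sprintf("%s ligand row %d", nm, row))
                    next
                }
                num <- tin[[it$number_item]][row]
                ins <- if (!is.na(it$ins_item)) tin[[it$ins_item]][row] else ""
                ch <- tin[[it$chain_item]][row]
                if (ins %in% c(".", "?")) ins <- ""
                hit <- which(!is.na(r$auth_res_num) &
                             r$auth_res_num == suppressWarnings(as.integer(num)) &
                             r$ins_code == ins & r$auth_chain_id == ch)
                if (length(hit) == 1L)
                    expect_equal(tout[[it$number_item]][row],
                                 as.character(r$new_number[hit]),
                                 label = sprintf("%s %s row %d", nm,
                                                 it$category, row))
            }
        }
    }
})

test_that("a residue gets the same new number in coordinates and annotations", {
    fx <- makeFixture(fixtureSpec(chainLength = 15, rule = "constant-offset",
                                  offset = 16, tagLength = 2), seed = 5)
    doc <- renumberMmcif(fx$mmcif, planFromFixture(fx))
    as_ <- cifTable(doc, "_atom_site")
    sc <- cifTable(doc, "_struct_conf")
    beg <- sc$beg_auth_seq_id
    expect_true(beg %in% as_$auth_seq_id)
    # the helix begin residue kept its comp_id pairing
    i <- which(as_$auth_seq_id == beg)[1]
    expect_equal(as_$auth_comp_id[i], sc$beg_auth_comp_id)
})

test_that("the scheme rewrite preserves originals as a three-way correspondence", {
    # author 18,19,20 must become 2,3,4 with originals archived
    fx <- makeFixture(fixtureSpec(chainLength = 10, rule = "constant-offset",
                                  offset = 16, uniStart = 1), seed = 6)
    doc <- renumberMmcif(fx$mmcif, planFromFixture(fx))
    ps <- cifTable(doc, "_pdbx_poly_seq_scheme")
    sel <- ps$auth_seq_num %in% c("18", "19", "20")
    expect_equal(ps$pdb_seq_num[sel], c("2", "3", "4"))
    expect_equal(ps$seq_id, as.character(1:10))       # 1-to-N untouched
    expect_equal(ps$ndb_seq_num, as.character(1:10))
})

test_that("an identity plan rewrites auth_seq_num with identical values", {
    fx <- makeFixture(fixtureSpec(chainLength = 8, rule = "identity"),
                      seed = 7)
    doc <- renumberMmcif(fx$mmcif, planFromFixture(fx))
    ps <- cifTable(doc, "_pdbx_poly_seq_scheme")
    expect_equal(ps$pdb_seq_num, ps$auth_seq_num)
})

test_that("the remark states the offsets actually configured", {
    fx <- makeFixture(fixtureSpec(chainLength = 6), seed = 8)
    d1 <- insertRemark(fx$mmcif)
    expect_match(cifTable(d1, "_database_PDB_remark")$text,
                 "50000\\+label_seq_id")
    d2 <- insertRemark(fx$mmcif, offsetConfig(mmcif = 70000))
    expect_match(cifTable(d2, "_database_PDB_remark")$text,
                 "70000\\+label_seq_id")
    expect_warning(d3 <- insertRemark(d1), "renumbered before")
    expect_length(cifTable(d3, "_database_PDB_remark")$id, 2L)
})

test_that("output naming carries the _renum tag", {
    expect_equal(renumFileName("2aa3", "mmcif"), "2aa3_renum.cif.gz")
    expect_equal(renumFileName("2aa3", "mmcif", gzip = FALSE),
                 "2aa3_renum.cif")
    expect_equal(renumFileName("2aa3", "mmcif", assembly = 1),
                 "2aa3-assembly-1_renum.cif.gz")
    expect_equal(renumFileName("2aa3", "legacy"), "2aa3_renum.pdb.gz")
    expect_equal(renumFileName("2aa3", "legacy", assembly = 1),
                 "2aa3_renum.pdb1.gz")
})

test_that("assembly chains inherit numbering from their source chain", {
    fx <- makeFixture(fixtureSpec(chainLength = 12, tagLength = 2,
                                  assemblyCopies = 3), seed = 9)
    plan <- planFromFixture(fx)
    pa <- extendPlanToAssembly(plan, fx$mmcif_assembly)
    expect_setequal(planChains(pa)$auth_chain_id, c("A", "B", "C"))
    doc <- renumberMmcif(fx$mmcif_assembly, pa)
    as_ <- cifTable(doc, "_atom_site")
    for (ch in c("A", "B", "C"))
        expect_equal(as_$auth_seq_id[as_$auth_asym_id == ch],
                     as.character(fx$expect$new_mmcif[!is.na(fx$expect$auth)]),
                     label = paste("assembly chain", ch))
})

test_that("a reference mmCIF reader parses our output identically", {
    # gemmi, via the system python, as an independent oracle on a tiny file
    fx <- makeFixture(fixtureSpec(chainLength = 6, tagLength = 1), seed = 10)
    doc <- renumberMmcif(fx$mmcif, planFromFixture(fx))
    tf <- withr::local_tempfile(fileext = ".cif")
    writeMmcif(doc, tf, gzip = FALSE)
    py <- Sys.which("python")
    expect_true(nzchar(py))
    out <- system2(py, c("-c", shQuote(paste0(
        "import gemmi,sys; d=gemmi.cif.read(sys.argv[1])[0]; ",
        "print(' '.join(d.find_loop('_atom_site.auth_seq_id')))")), tf),
        stdout = TRUE)
    expect_equal(strsplit(out, " ")[[1]],
                 cifTable(doc, "_atom_site")$auth_seq_id)
})
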