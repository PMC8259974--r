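# unirenum

Renumber macromolecular structure files to UniProt numbering.

## The problem

Depositors to the PDB may number the residues of a protein chain any way
they like: with or without the initiator methionine, with or without a
cleaved signal peptide, continuing a tag with negative numbers, or using
insertion codes (100, 100A, 101, ...). The same protein therefore carries
different residue numbers in different entries — the DFG motif of the human
IGF1R kinase is 1153–1155 in one entry and 1123–1125 in another, purely
because the second follows the mature-protein numbering that omits the
30-residue signal peptide. Every comparative analysis, and every attempt to
map sequence-level annotation onto structures, has to fight this.

`unirenum` fixes the numbering at the file level. Using the residue-by-residue
PDB↔UniProt correspondences published by PDBe's SIFTS resource, it rewrites
mmCIF and legacy PDB files (asymmetric units and biological assemblies) so
that every author residue number — in the coordinates *and* in every
residue-numbered annotation table — becomes the UniProt residue number.

## The renumbering scheme

For a chain mapped to a UniProt sequence, each residue's new number is

* **UniProt number**, when SIFTS provides one (mutated residues keep the
  structure's residue type together with the UniProt number);
* **offset + label_seq_id** (the chain's 1-to-N position) for residues with
  no UniProt number, such as expression tags: offset 50 000 in mmCIF output
  and 5 000 in legacy PDB output, so these can never collide with genuine
  UniProt numbers;
* non-polymer groups (ligands, waters) get **60 000 + original number** in
  mmCIF output; in the legacy format, where numbers cannot exceed 9999, they
  are instead reassigned the largest numbers still free in 1..9999, in
  reverse order.

Chains with no UniProt correspondence are left untouched. Chimeric chains
mapping to several accessions keep all of them when their UniProt ranges do
not clash (flag `+`); on a clash the accession covering the most residues
wins (flag `*`), skipping a configurable list of crystallization chaperones
(GFP_AEQVI, GCN4_YEAST, C562_ECOLX, ENLYS_BPT4, MALE_ECOLI).

The original numbering is not lost: in the output's
`_pdbx_poly_seq_scheme` table, `pdb_seq_num` holds the new numbering and
`auth_seq_num` archives the numbering of the original file, giving a
three-way 1-to-N ↔ UniProt ↔ original correspondence. A provenance remark
describing the scheme (with the offsets actually used) is inserted into
every output file, and outputs carry the `_renum` name tag
(e.g. `2aa3_renum.cif.gz`).

## Worked example

The package ships a synthetic fixture generator that produces mutually
consistent SIFTS XML + mmCIF + legacy PDB triples for all the pathological
cases (it is also how the test suite works offline). A chain whose author
numbering is UniProt + 16, behind a two-residue His tag:

```r
library(unirenum)
fx   <- makeFixture(fixtureSpec(chainLength = 10, rule = "constant-offset",
                                offset = 16, tagLength = 2,
                                ligands = data.frame(name = "ZN", number = 5)),
                    seed = 3)
rec  <- parseSifts(fx$sifts_xml)
plan <- assignTargetNumbers(rec, resolveChainAccession(rec))
plan
#> RenumberPlan (mmcif): 10 residue(s) across 1 chain(s)
#>  auth_chain_id accession uni_len chain_len renum offset_count flag
#>              A    P00001       8        10     8            2

doc <- renumberMmcif(fx$mmcif, plan)
head(cifTable(doc, "_atom_site")[, c("auth_seq_id", "label_seq_id")], 4)
#>   auth_seq_id label_seq_id
#> 1       50001            1
#> 2       50002            2
#> 3           1            3
#> 4           2            4
```

The two tag residues became 50001 and 50002 (50 000 + position), the mapped
residues took their UniProt numbers (author 19 → 3, etc.), and the zinc ion
became 60005. `writeMmcif(doc, "...")` writes the result. The same plan in
legacy form (`format = "legacy"`) gives the tag 5001/5002 and hands the zinc
9999, the largest free legacy number.

Batch use mirrors a command-line tool (a wrapper script is installed under
`inst/scripts/unirenum`): `runBatch(c("1d5t","1bxw"), c("mmCIF","PDB"))`
fetches inputs (with three-attempt retry), renumbers each entry, writes
outputs under `output_mmCIF/` etc., and returns the per-chain log (TSV) with
columns `PDB_id, chain_PDB, chain_auth, UniProt, SwissProt, uni_len,
chain_len, renum, 5k_or_50k, SP`.

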