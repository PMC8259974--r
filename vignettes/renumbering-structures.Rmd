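---
title: "Renumbering structure files to UniProt numbering"
author: "unirenum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Renumbering structure files to UniProt numbering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unirenum)
```

## The model

Author residue numbering in archived structure files is free-form: the same
protein can be numbered from the preprotein, from the mature protein, from a
construct, or idiosyncratically, and expression tags may carry negative
numbers or none at all. `unirenum` replaces the author numbering with the
UniProt numbering, taking the residue-level PDB↔UniProt correspondence from
SIFTS as given — no alignment is recomputed here; SIFTS is trusted as the
authority on which structure residue corresponds to which UniProt position.

For every polymer residue, SIFTS supplies the chain's canonical 1-to-N
position (`label_seq_id`), the author number plus optional insertion code,
the residue name, and — where the residue belongs to a UniProt sequence —
the accession and UniProt residue number. The target number is then

* the UniProt number, for residues with one under the accession in force
  for their chain (mutated residues keep the structure's residue type with
  the UniProt number);
* `offset + position` for residues of UniProt-bearing chains with no
  UniProt number (tags, linkers);
* nothing, for chains with no UniProt correspondence — they are left
  byte-identical.

Non-polymer groups are renumbered `ligand offset + original number` in
mmCIF; in the legacy format they are reassigned the largest numbers still
free in 1..9999, in file order from the top down, because the fixed columns
cannot hold a 60 000-range number.

## Parameters

| parameter | default | meaning |
|---|---|---|
| mmCIF tag offset | 50 000 | added to 1-to-N position of non-UniProt residues in mmCIF output |
| legacy tag offset | 5 000 | same, legacy PDB output (kept below the 9999 column cap; values above 9000 draw a warning) |
| mmCIF ligand offset | 60 000 | added to non-polymer residue numbers in mmCIF output |
| chaperone exceptions | 5 IDs | accessions skipped when a chimera's numbering clashes |
| retry bound | 3 | download attempts before a resource is declared absent |

All offsets live in one `offsetConfig()` object and are substituted into the
generated provenance remark, so the remark in an output file always states
the offsets that were actually applied to it. The offsets must exceed every
genuine UniProt number in the entry whenever tag residues are present;
violating that raises a collision error telling the user to pick a larger
offset, rather than producing an ambiguous file. The check is deliberately
restricted to entries that actually contain offset-numbered residues: a
chain legitimately author-numbered above 5 000 (a large protein in legacy
format, say) with no tags has nothing to collide with.

The chaperone exception list is configuration, not code: it is read from
`extdata/chaperone_exceptions.txt` (one identifier per line, SwissProt-ID or
accession form) so it can grow without a code change.

## Resolution of chimeric chains

A chain mapping to several accessions is renumbered by all of them when
their UniProt number ranges do not overlap (each segment by its own
accession; flagged `+` in the log). Overlap is decided on the closed integer
ranges spanned by each accession's UniProt numbers. When ranges clash, the
accession covering the most residues wins (flag `*`), skipping accessions on
the chaperone exception list; an equal-coverage tie breaks to the
lexicographically smallest accession so that output is deterministic. The
special case of a single chain mapping twice to the *same* accession over
disjoint segments needs no resolution at all — every residue carries its own
UniProt number.

## What is rewritten, and how

In mmCIF, renumbering touches exactly the vetted static list of residue-number
items that are dictionary children of `_atom_site.auth_seq_id` (plus
`pdb_seq_num` in the three sequence-scheme tables and
`_struct_ref_seq_dif.pdbx_auth_seq_num`, which corresponds to `pdb_seq_num`).
Each item is paired with its author chain-id column (`auth_asym_id` /
`pdb_strand_id` / `pdbx_strand_id` variants) and insertion-code column, and
rows are matched on the (author number, insertion code, author chain) key.
Dictionary-driven discovery of further variants is deliberately a fallback
that only logs novel items: silently renumbering an unvetted item risks
corrupting a table whose semantics differ (the one known `pdbx_auth_seq_num`
exception is the cautionary example). Values are strings end to end — no
numeric reformatting ever touches columns the plan does not name, and the
null markers `.` and `?` pass through untouched.

The three scheme tables serve a second purpose: after `pdb_seq_num` is
renumbered, the *original* `pdb_seq_num` values are written into
`auth_seq_num`, replacing historical deposition data that today's files no
longer use elsewhere. The output thereby contains an explicit three-way
correspondence (1-to-N, new numbering, original numbering), which is also
how a user can always recover the original numbers.

In the legacy format, substitution is key-targeted fixed-column rewriting:
for `ATOM`/`HETATM`/`TER`/`ANISOU`/`SIGUIJ` records the 9-character key
`AuthResNum(4) + InsCode(1) + ResName(3) + ChainID(1)` is read from the
wwPDB v3.3 columns (resSeq 23–26, iCode 27, resName 18–20, chainID 22) and,
on a match, exactly the number and insertion-code columns are rewritten at
identical width. A global string replacement over the raw line — the obvious
alternative — can corrupt coincidental matches elsewhere on a line (serial
numbers, coordinates), so it is not used, although the observable behavior
on well-formed files is the same. `REMARK 465` rows (missing residues) are
keyed from their own columns; rows whose residue has no author number in
SIFTS at all are matched per chain in file order against the unobserved
records, requiring residue-name agreement, because nothing else on a
REMARK 465 line identifies the 1-to-N position.

Insertion codes are carried through unchanged in both formats; if two
residues of a chain would end up with the same (number, insertion code)
pair, the plan construction fails loudly rather than merging them. Whether
codes *should* be cleared once residues obtain unique UniProt numbers is an
open design question; keeping them is the conservative choice that preserves
the author's identifiers.

Biological assembly files give every chain copy its own unique author chain
id. Assembly chains are matched back to their source chain by requiring an
identical set of (author number + insertion code, residue name) signatures
over the polymer residues; matched copies inherit the source numbering and
mismatches are reported and left untouched.

## Numerical and degenerate-input choices

* Unobserved residues are modelled as *absent* author numbers, not as a
  sentinel integer; their replacement numbers flow through the seq-position
  key. A sentinel would risk colliding with a genuine number.
* Negative author numbers are parsed as signed integers occupying the same
  fixed columns.
* The collision threshold is `>= offset`, not `> offset`: the separation
  between UniProt-derived and offset-derived numbers is strict.
* Legacy chains whose new numbers cannot be rendered in 4 characters
  (above 9999 or below −999) are excluded from the legacy output with a
  warning — never truncated.
* Renumbering its own output is not idempotent and is not claimed to be;
  a second run is detected through the provenance remark and flagged.
* Waters follow the non-polymer (ligand) rule; the alternative of leaving
  them untouched risks collisions with renumbered polymer residues.

## The synthetic fixture generator

`makeFixture()` emits mutually consistent SIFTS XML + mmCIF + legacy PDB
triples for one chain, covering: identity numbering, constant offsets,
signal-peptide (mature-protein) numbering, tags with negative or absent
numbers, insertion codes, clashing and non-clashing chimeras, chains with no
UniProt mapping, and non-polymer ligands, with optional assembly copies —
together with the renumbering the construction implies, as an expectation
table. The generator emulates the *numbering pathology* of real files, at
minimal but schema-valid scale: single CA atoms, plausible but meaningless
coordinates, one chain per entry, compact SIFTS XML. It does not emulate
multi-model files, branched sugars, micro-heterogeneity, or the full
annotation-table menagerie of production mmCIF — so passing tests demonstrate
the numbering logic, not robustness to every archival quirk. Parsers are
exercised on the same dialects they read in production (fixed columns,
loop/key-value mmCIF, SIFTS residue XML).

Default fixture conditions follow the scenarios the method is designed
around: tag offsets of 50 000/5 000/60 000, a 30-residue signal-peptide
shift, 80/20 chimera splits. Test problem sizes (chains of 5–160 residues,
batches of four entries) are desk-scale by design; the numbering rules are
exact and size-independent, so small fixtures prove them as well as large
ones.

## Network behavior

All HTTP access is isolated in one module behind an injectable fetcher
closure, with three-attempt retry; after three failures a resource is
declared absent and the entry is skipped with a log record. Endpoints
(RCSB for asymmetric units, PDBe for assemblies and SIFTS) are configuration
with those defaults. The rest of the package, and the whole test suite, run
offline on fixtures.

## Known limitations

* SIFTS is trusted as given; entries whose SIFTS mapping is wrong come out
  wrong.
* `CONECT` serial remapping, `SEQRES`/`DBREF` rewriting and hybrid-36
  numbering are out of scope for the legacy writer.
* `REMARK 470/480` residue lists are not rewritten (only `REMARK 465` is).
* The mmCIF writer reproduces every value but not the byte layout
  (column alignment) of the input file.
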