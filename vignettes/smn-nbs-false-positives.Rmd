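---
title: "Resolving primer-site false positives in SMA newborn screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving primer-site false positives in SMA newborn screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smnscreen)
library(tibble)
```

## The problem

PCR-based newborn screening (NBS) for spinal muscular atrophy (SMA) reports
the *absence* of SMN1 exon 7: a newborn with no amplification signal from
either allele is flagged as having a bi-allelic SMN1 deletion. The assay can
be fooled. A rare sequence variant lying under a primer or probe abolishes
amplification of an allele that is otherwise intact, and the screen then
reports a deletion that is not there. Resolving such a result requires four
separate computations, and this package implements each of them as a tested,
reusable unit:

1. **Protein consequence of the candidate variant** (`protein_consequence()`):
   what does the variant do to the protein, in HGVS p. nomenclature?
2. **Dropout screening** (`screen_variants()`): does the variant overlap a
   primer- or probe-annealing interval, and how likely is that overlap to
   abolish amplification?
3. **Transcript discrimination by restriction digest**
   (`classify_transcript()`): when SMN1 and SMN2 transcripts must be told
   apart experimentally, DdeI digestion cuts specifically within the SMN2
   exon-8 sequence; the in-silico digest reproduces that read-out and scores
   full-length versus exon-7-skipped (Δ7) isoforms.
4. **Population arithmetic** (`risk_report()`): given carrier counts for the
   candidate variants and the known SMN1-deletion carrier frequency, how many
   compound heterozygotes (deletion *in trans* with the variant) should exist,
   and how many such newborns should a screening programme encounter per year?

## The consequence engine

The engine works by comparison of translated proteins rather than by case
analysis on the variant description. A variant is applied to the transcript
(with the stated reference allele checked against the sequence — the main
defence against coordinate errors), the reference CDS and the mutated
sequence are both translated, and the first differing residue is located.
Translation of the mutated sequence continues past the reference stop codon
into the 3'UTR, because a shifted reading frame usually terminates there.

The call logic is:

* no differing residue → synonymous;
* frame-preserving, single residue changed → missense, or nonsense if the new
  residue is a stop;
* frame-preserving, several residues changed → in-frame indel (`p.del`,
  `p.ins`, `p.delins` naming). These never receive `fsTer` nomenclature;
* frame-shifting → frameshift `p.<Ref><pos><Alt>fsTer<offset>`, where the new
  stop is counted with the first changed residue as position 1. If the first
  changed codon is itself a stop, the call is nonsense (`p.XxxNTer`) rather
  than `fsTer1`, per HGVS convention; if the shifted frame reaches the end of
  the transcript without a stop, the kind is `no_stop_found` rather than a
  guessed extension.

```{r consequences}
m <- smn_transcript_demo()
for (h in c("c.855_858delAGAA", "c.861_864delAAGG",
            "c.861_862insT", "c.863G>T"))
  cat(h, "->", protein_consequence(m, h)$hgvs_p, "\n")
```

The two recurrent 4-bp deletions are distinct events that produce the same
frameshift, p.Arg288AlafsTer5: after either deletion the next three codons
still encode the reference residues 285–287, the first changed residue is 288
(Ala), and the shifted frame meets a TAA five codons in. The neighbouring
known variants act as mutual consistency checks: codon 288 must be AGG for
c.863G>T to give Met288 and for c.861_862insT to create an immediate TAG stop
(p.Arg288Ter). No right-shift (3') normalisation is applied before
consequence calling — the two deletions are applied exactly as written, which
is also why they remain distinguishable events at the DNA level while sharing
a protein consequence.

### The demonstration transcript

`smn_transcript_demo()` is a synthetic SMN1-like transcript: a 60-nt 5'UTR,
an 885-nt CDS (294 residues plus stop) across 8 exons, with the stop codon
inside exon 7 and exon 8 entirely untranslated, as in the real SMN genes. Its
exon-7 coding region (c.835–885) is exactly the published SMN1 exon-7
sequence, which the four variant consequences above jointly determine; the
remainder of the transcript is deterministic synthetic filler. It is a
reconstruction sufficient for every exon-7 computation in this package, not a
copy of the GenBank transcript record, and it is documented as such.

## Dropout screening

Assays are user-supplied configuration: a set of components (forward primer,
reverse primer, probe), each an interval in transcript c. space. The genomic
primer sequences of commercial NBS kits are proprietary, so the bundled
`demo_assay()` is illustrative — its reverse-primer interval (c.850–876) is
chosen to contain both recurrent deletions, reproducing the mechanism rather
than any kit's true coordinates.

The classification cascade is deliberately conservative:

* any indel overlapping any component → `likely_dropout_indel`;
* a substitution within `three_prime_window` bases of a primer's 3' terminus
  (default 5, a standard PCR rule of thumb; no published threshold exists for
  these kits) → `likely_dropout_3prime_substitution`;
* any other overlapping substitution, probes included →
  `at_risk_substitution`, because a single internal mismatch often still
  amplifies;
* otherwise → `no_overlap`.

Primer 3' polarity follows transcript orientation: the forward primer's 3'
end is its right interval boundary, the reverse primer's its left. Probes
have no polarity and are treated like primers for set membership (the
screen does not distinguish probe-binding from primer-binding regions when
collecting the annealing-region variant set).

```{r screen}
tab <- make_variant_table(seed = 7)
rep <- screen_variants(tab, demo_assay())
glance(rep)
```

## The in-silico digest

DdeI (C^TNAG) is encoded with its cut one base after the motif start. CTNAG
is its own reverse complement, so a single-strand scan finds every site;
asymmetric enzymes are scanned on both strands generically. Fragment lengths
always partition the input. The transcript classifier makes the gene call the
way the wet assay does — by whether a cut falls inside the paralogous exon-8
window — and the isoform call by presence of an exon-7 tag subsequence.
Because no fragment sizes are published for this read-out, classification is
by presence/absence of the informative cut, never by absolute band size.
Amplicons must match one of the four candidate templates (each paralog,
full-length or Δ7) exactly by default (`max_mismatch = 0`); anything else is
reported unclassifiable rather than force-fitted.

```{r digest}
pair <- make_paralog_pair(seed = 42)
amps <- paralog_amplicons(pair)
purrr::imap_dfr(amps, function(s, id)
  dplyr::mutate(classify_transcript(s, pair$a, pair$b, pair$exon7_tag,
                                    pair$exon8_window), record = id))
```

## The population model

All epidemiology is Hardy–Weinberg arithmetic with explicit, recorded
rounding. Carrier frequencies are computed over carrier *individuals*, not
alleles (60 heterozygotes, not 60 alleles; 111 Europeans, not 112 alleles).
The compound-heterozygote frequency is

$$ f_{\text{chet}} \;=\; f_{\text{del}} \times f_{\text{vus}} \times \tfrac14, $$

the product of the two carrier frequencies with one Mendelian quarter (each
carrier parent transmits its variant allele with probability 1/2). A strict
random-mating derivation that counts both assignments of the two allele
classes to the two parents would add a factor 2; that variant is available as
`count_parent_orders = TRUE` but is off by default, keeping the quarter-factor
convention. The assumptions — random mating, no consanguinity, no fitness
effects, no ancestry substructure within the stratum — are those of any
carrier-frequency product estimate.

Because headline numbers are quoted from rounded intermediates, the chain is
computed on two labelled paths. `rounding = "display"` feeds each step the
previous step's displayed value; `rounding = "exact"` carries full precision.
The display conventions are fixed and recorded in the provenance of every
estimate: carrier reciprocals truncate; a compound-het reciprocal at or above
one million displays in millions truncated to two decimals, below that it
rounds to an integer; expected individuals floor; expected annual births
truncate to one decimal below 3 and round to an integer at 3 or above.

```{r epi}
recs <- tibble(variant_id = c("855del4", "861del4"),
               carrier_count = c(13L, 47L), n_individuals = 589724L)
risk_report(recs, cohort_preset("eu"))

risk_report(tibble(carrier_count = 111L, n_individuals = 589724L),
            cohort_preset("eu"), rounding = "exact")
```

The `"eu"` preset carries the cohort constants: 1.13 billion individuals of
European descent (13.88% of 8.2 billion), 3.67 million annual EU27 births,
64% SMA-NBS coverage, and an SMN1-deletion carrier frequency of 1/35 in
Europeans. Coverage defaults to *not* being applied — the headline annual
expectation is over all births — and enters only with
`apply_coverage = TRUE`.

## What the synthetic generator emulates — and what it does not

`make_scenario()` produces every input the pipeline reads: a paralog pair
differing at declared discriminating positions (one of which creates the
exon-8 DdeI site in the second paralog only, echoing the real SMN1/SMN2
c.840 and exon-8 differences), the demo assay, a variant table of rare,
exclusively heterozygous annealing-region variants whose first two rows are
always the two recurrent 4-bp deletions, and the EU cohort constants. The
paralog models default to 8 exons of 111 nt (an 888-nt transcript, the scale
of the real SMN transcripts) with the stop codon placed inside exon 7.

`simulate_newborn_cohort()` draws two alleles per newborn from {wild-type,
deletion, VUS} and computes the screen result mechanistically: an allele
yields signal unless it is the deletion (no template) or a VUS whose dropout
call is dropout-level. The simulation operates at *allele* level (genotype
frequencies $p^2$, $2pq$), whereas the reporting chain operates at *carrier*
level with the 1/4 factor; for rare alleles $2\,p_{\text{del}}\,p_{\text{vus}}
\approx (2p_{\text{del}})(2p_{\text{vus}})/2$, and the test suite reconciles
the two explicitly rather than hiding the distinction.

What passing tests on synthetic data do **not** show: the generator draws
carrier counts uniformly rather than from a realistic site-frequency
spectrum, models no population substructure, linkage, de novo events or gene
conversion, and its transcripts are filler outside the constrained exon-7
region. Agreement on synthetic data validates the arithmetic and the
interval logic, not any property of real screening cohorts.

## Numerical and design choices

* Internal coordinates are 1-based closed throughout, with HGVS conversion
  confined to `c_to_index()` / `index_to_c()` — one conversion boundary, no
  off-by-one drift. Intronic offsets (`c.100+3`) are rejected loudly: the
  models are spliced transcripts and silently mis-mapping would be worse than
  failing.
* Genomic (g.) coordinates are out of scope; assays are declared in c. space
  because the published reasoning is entirely transcript-relative.
* Overlap of closed intervals is `max(0, min(ends) − max(starts) + 1)`;
  adjacency is not overlap. Tied component overlaps resolve forward primer,
  then reverse primer, then probe.
* Splice-impact prediction is deliberately absent. The known complete
  exon-7 skipping caused by c.863G>T is an experimental finding; it can be
  carried as an `annotation_flags` entry but is never computed.
* The consequence-oracle and digest-oracle test suites run 1,000 randomized
  cases each; the cohort simulation runs 20 replicates of 4×10⁶ newborns.
  These sizes make the binomial comparison sharp (the compound-het
  expectation is ≈5.8 per cohort) while keeping the default test run fast.
* Scenario generation, the demo transcript and the simulator are
  deterministic given a seed; identical seeds yield byte-identical outputs.

## Limitations

* No thermodynamic annealing model: dropout calls are interval logic, not ΔG
  or melting-temperature predictions.
* HGVS support covers small coding variants (sub/del/ins/dup/delins);
  extensions, inversions, repeats and intronic positions are rejected.
* The epidemiology reports no confidence intervals, matching the point-count
  inputs it is designed around; binomial uncertainty on small carrier counts
  is substantial.
* The demo transcript's filler regions make it unsuitable for any analysis
  outside the constrained exon-7 window.
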