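# fosmidann

Gene-neighborhood annotation of fosmid insert sequences from gene-dense
plant genomes, modeled on the annotation workflow used for targeted
~30–45 kb genomic clones of diploid strawberry (*Fragaria vesca*).

## What it does

Given a set of fosmid inserts (FASTA, optionally multi-contig), protein
homology hits (12-column BLAST tabular), spliced EST alignments and ab
initio gene-prediction tracks (GFF3), the package produces a per-insert
neighborhood annotation and study-level summary tables:

- **SSR survey** — maximal perfect microsatellites with unit length
  2–5 bp and ≥ 5 repeat units (SSRIT-style parameters). Tracts are
  reported under their primitive motif only (an (AT)₁₀ is never also an
  (ATAT)₅), classes are canonicalized by cyclic rotation (and reverse
  complement for dinucleotides, so AG = AG/GA/CT/TC), and tracts separated
  by < 100 bp are merged into *operational SSR loci* — the unit one primer
  pair would genotype. Densities: tracts/Mb, kb per tract, kb per locus,
  and the map-distance extrapolation loci/cM via the genome-wide kb/cM
  ratio.
- **Homology-inferred gene sites** — hits filtered at a relaxed cutoff
  (E ≤ 1e-5), chained per subject/strand across introns, merged across
  paralogous subjects, and tiered *strict* (E ≤ 1e-10) vs *relaxed*.
  Start/stop codons are located by frame-anchored scans (first in-frame
  stop at/after the homology 3′ end; the anchor ATG or the farthest open
  upstream in-frame ATG at the 5′ end), truncation is flagged
  (artifactual at insert ends, contig-break, biological/pseudogene-like),
  and tandem duplicates are detected and oriented (head-to-tail,
  head-to-head, tail-to-tail).
- **EST support** — alignments tiered top (≥ 95% identity) / second
  (85–94%), per-gene coverage classified complete/partial/none at base
  level (splice gaps within one EST are credited), EST-only gene sites
  detected, and exon/intron gene models built where coverage is complete,
  with intron statistics (mean introns per gene, length distribution).
- **Prediction reconciliation** — each ab initio track is scored against
  the evidence-based sites: unsupported predictions, gene mergers (and
  genes merged), splits, and start/stop codons validated by exact
  coordinate agreement.
- **Microsynteny** — colinearity and conserved microsynteny between insert
  gene order and a reference gene order encoded by AGI-style locus codes
  (`At3g54340`; nominal step 10 within a chromosome).
- **Synthetic studies** — `simulate_study()` generates seed-reproducible
  inserts with planted genes, SSRs, TE-related sites, contig gaps,
  corrupted prediction tracks and EST alignments, with ground truth
  sufficient to predict every pipeline output exactly.

## Worked example

```r
library(fosmidann)

st  <- simulate_study(sim_config(seed = 1, n_inserts = 20))
rep <- run_pipeline(st$records, st$hits, st$ests, st$tracks)
rep
#> <neighborhood_report> 20 insert(s), 157 gene site(s), 168 SSR tract(s) in 150 locus/loci
#> <density_summary>
#>   20 insert(s), 745,541 bp total (mean 37,277 bp)
#>   143 non-TE gene sites: 1 per 5.2 kb
#>   SSR: 225 per Mb, 1 locus per 5.0 kb
#>   map: 486 kb/cM, 97.8 SSR loci per cM
```

The density block reads: 20 simulated inserts totalling 745,541 bp; one
protein-coding gene site (TE-related and EST-only sites excluded) per
5.2 kb; 225 SSR tracts per Mb with one operational locus per 5.0 kb; and,
extrapolating through the 206 Mb / 424 cM genome context (486 kb/cM),
about 98 SSR loci per centimorgan of map distance. The same arithmetic on
the real study inventory (`inst/extdata/fosmid_inventory.tsv`, 708,363 bp
over 20 inserts) gives one gene per 5.9 kb from 120 sites, one SSR tract
per 4.5 kb from 158 tracts, and one operational locus per 4.9 kb from 144
loci.

Single stages are ordinary functions:

```r
scan_ssrs(paste0(strrep("TCC", 6), "TCT", strrep("TCC", 5)))
#>   insert_id start end motif canonical_motif unit_length repeat_count
#> 1       seq     1  18   TCC             CCT           3            6
#> 2       seq    22  36   TCC             CCT           3            5
```

— an interrupted repeat is two tracts (3 bp apart), which
`merge_operational_loci()` then joins into one operational locus.

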