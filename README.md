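# utrcode

Rule-based prediction of maternal-mRNA translational behaviour in mouse
oocytes from 3'-UTR cis-element geometry.

Fully grown (germinal-vesicle, GV) oocytes are transcriptionally silent;
which stored mRNAs are translated, and when, is written in their 3'-UTRs
as a combinatorial code of two elements: the polyadenylation signal
(PAS, AAUAAA), which recruits CPSF and nucleates cytoplasmic
polyadenylation, and the CPEB1-bound cytoplasmic polyadenylation element
(CPE), which represses nearby PASs before meiotic resumption and
stimulates them afterwards. `utrcode` is for researchers studying
post-transcriptional control in oocytes (or anyone who needs a motif-
geometry rule engine): it scans 3'-UTRs for PAS/CPE/PBE motifs, rebuilds
reporter constructs in silico, and predicts per-stage activity and
transcript fate.

## The code, formally

Each PAS *p* is classified by the spacer gaps to the CPEs around it,
with two windows `w_one = 40` nt and `w_flank = 100` nt:

```
call(p) = FLANKED    if >= 1 CPE within w_flank on each side
          ONE_SIDED  if CPEs within w_one on exactly one side
          FREE       otherwise
```

GV-stage activity per PAS: `FREE -> 1`, `FLANKED -> 0`,
`ONE_SIDED -> max(0, 1 - 0.5 - 0.25 (n - 1))` for `n` in-window CPEs.
Transcript GV activity is the mean contribution over the wild-type's
translation-competent PASs (so a construct retaining one of two
competent PASs scores 0.5). After GVBD every PAS becomes accessible
(activity 1) and gains `0.5` per CPE within `w_flank` — repressors
turned stimulators — which forces post-GVBD ≥ GV activity. Fates:
`CONSTITUTIVE_GV`, `GV_ACTIVE_BOOSTED`, `DORMANT_ACTIVATED`,
`INACTIVE`. All parameters live in `code_config()` and a YAML config.

## Worked example

The three packaged fixtures reproduce the Cpeb1-, Btg4- and Cnot6l-like
architectures on synthetic motif-free backgrounds:

```r
library(utrcode)
fx  <- paper_fixtures()
cfg <- code_config()

fx$Cnot6l$architecture
#> UtrArchitecture 'Cnot6l' (1597 nt): 6 element(s)
#>  label element_class start  end matched_seq
#>   PAS1           PAS    40   46      AATAAA
#>   CPE1           CPE   196  203     TTTTAAT
#>   CPE2           CPE  1417 1424     TTTTAAT
#>   CPE3           CPE  1477 1484     TTTTAAT
#>   PAS2           PAS  1544 1550      AATAAA
#>   CPE4           CPE  1560 1567     TTTTAAT

predict_profile(fx$Cnot6l$architecture, cfg)
#> TranslationProfile 'Cnot6l': GV 0.5, post-GVBD 1.5 -> GV_ACTIVE_BOOSTED
#>  pas_label    call n_up n_down n_one nearest_gap gv post_gvbd
#>       PAS1    FREE    0      0     0         150  1         1
#>       PAS2 FLANKED    1      1     1          10  0         2
```

The proximal PAS1 sits 150 nt from the nearest CPE and is free: it alone
drives GV-stage translation. The distal PAS2 is flanked (a CPE 60 nt
upstream, another 10 nt downstream) and contributes nothing at GV but is
stimulated after GVBD. Truncating the UTR to its distal 402 nt — the
fragment used in an earlier reporter study — removes PAS1 and flips the
transcript to dormant-then-activated:

```r
tr <- truncate_distal(scan_utr(fx$Cnot6l$record), 402)
predict_profile(tr$arch, cfg)
#> TranslationProfile 'Cnot6l': GV 0, post-GVBD 2 -> DORMANT_ACTIVATED
```

`evaluate_constructs()` scores the full packaged set of 32 reporter
constructs (PAS/CPE mutations, spacer deletions, CPE insertions,
truncation) against their observed outcomes; with defaults it reproduces
31/32 GV-stage calls and 7/7 post-GVBD directions, and prints the one
known mismatch with its figure anchor (see the methods vignette,
`vignettes/utr-code.Rmd`, for why that construct is a genuine granularity
limit of the one-sided rule).

A thin CLI covers the same surface:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","utrcode.R",package="utrcode"))')" \
    predict --fasta my_utrs.fa --stage both --out report.tsv
```

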