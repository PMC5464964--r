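# pcnatrack

Quantitative cell-cycle analysis of fluorescence time-lapse movies in which a
single endogenously tagged PCNA channel carries all cell-cycle information.

PCNA (proliferating cell nuclear antigen) is the replication sliding clamp.
Expressed from its endogenous locus, one fluorescent PCNA allele reports the
whole cell cycle at low magnification without any further marker:

- nuclear PCNA abundance stays **low and flat through G1**, then rises about
  **2-fold across S phase** to a G2 plateau — the onset of the rise marks the
  **G1/S transition**;
- during S phase the reporter concentrates in growing replication foci, so
  the **within-nucleus intensity distribution width** (pixel SD) rises and
  peaks at the **end of S phase** — the width maximum marks the **S/G2
  transition**;
- at **nuclear envelope breakdown (NEBD)** the reporter disperses into the
  cytoplasm, producing an abrupt drop of the nuclear mean that marks
  **mitosis**, cross-checkable against the width spike of a chromatin marker
  as the chromosomes condense;
- on cell-cycle exit, PCNA expression ceases and the nuclear signal
  **declines gradually over ~48 h** — the signature of **quiescence (G0)**.

`pcnatrack` implements the full workflow for 2-D multi-channel TIFF stacks:
nucleus segmentation on the PCNA (or a chromatin) channel with a
post-tracking local re-segmentation step that recovers dim G1 nuclei;
overlap-based tracking with gap closing, division detection and lineage
assembly; classification of G1, S, G2, M and G0 from the PCNA features
alone; and quantitative nuclear/cytoplasmic extraction of co-imaged
reporters (e.g. tagged cyclins), corrected to total-protein estimates via
tagged-allele fractions and exposure standardization. A ground-truthed
synthetic movie generator emulating all of these reporter dynamics makes
every stage testable without external data.

Intended users: quantitative cell biologists and image-analysis developers
working with endogenous cell-cycle reporters, and anyone needing a
self-validating reference pipeline for PCNA-based phase classification.

## Worked example

Simulate a small ground-truthed movie (six founder cells, 100 frames at
15-min intervals, with PCNA, chromatin and a cyclin-A2-like channel) and run
the full analysis:

```r
library(pcnatrack)

params <- simulation_params(n_cells = 6, n_frames = 100, frame_interval = 15,
                            image_size = c(200, 200), seed = 42,
                            coreporter_onset_offsets = c(cycA2 = 45))
movie <- simulate_movie(params)
#> <synthetic_movie> 14 cells (6 founders), 100 frames @ 15 min, channels: pcna, chromatin, cycA2

analysis <- process_movie(movie$stack)
#> <movie_analysis> 14 tracks (seg: pcna), 4 divisions, 6 G1/S onsets

analysis$annotations[["2"]]
#> <phase_annotation> track 2 | birth=1 g1s=7 sg2=43 nebd=62 division=64

report_movie(analysis)
#> <movie_report>
#>   tracks: 14, divisions: 4
#>   G1: 7.2 +/- 4.2 h (n=6)
#>   S:  9.6 +/- 0.4 h (n=4)
#>   G2: 4.2 +/- 0.4 h (n=4)
#>   quiescent fraction: 0.00
```

Track 2 is born at frame 1, enters S phase at frame 7 (1.5 h), reaches the
replication-foci width maximum at frame 43 (10.5 h, end of S), undergoes
NEBD at frame 62 and divides at frame 64 — whereupon the lineage records its
two daughters. The report aggregates phase lengths across the movie: G1
7.2 ± 4.2 h, S 9.6 ± 0.4 h and G2 4.2 ± 0.4 h here, against generator
settings of G1 ~ 7.7 ± 3.0 h, S = 10 h and G2 = 4 h.

Converting a single-allele fluorescence measurement to a total-protein
estimate uses the tagged-allele fraction (e.g. a tagged allele carrying 30%
of the total pool):

```r
correct_for_tagged_fraction(3.0, f = 0.30)
#> [1] 10
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/pcnatrack`:

```sh
Rscript inst/scripts/pcnatrack all --config config.yml --seed 7 --output out/
```

with subcommands `simulate`, `segment`, `track`, `classify`, `quantify`,
`report` and `all`, YAML configuration, and CSV/TIFF/structured-text outputs
carrying the producing config hash.

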