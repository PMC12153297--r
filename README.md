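# punctadyn

Quantitative analysis of diffraction-limited fluorescent puncta in rod-shaped
bacteria — built for flagellar basal bodies visualized through GFP-tagged
C-ring subunits, and applicable to any membrane complex that appears as a
spot. The package answers three questions about such puncta:

1. **Do they move?** Single-particle tracking of time-lapse movies
   (Laplacian-of-Gaussian detection, radial-symmetry sub-pixel localization,
   nearest-neighbour linking) followed by rolling-segment mean-squared
   displacement analysis. For Brownian motion with localization noise,

   ⟨r²⟩(τ) = 4 D_app τ + 4 σ²,

   and D_app is estimated per 20-frame segment as ¼ of the weighted
   least-squares slope of ⟨r²⟩ against lag time τ, weighting each lag by its
   displacement count nᵢ:

   D_app = ¼ · (Σnᵢ Σnᵢτᵢ⟨r²⟩ᵢ − Σnᵢτᵢ Σnᵢ⟨r²⟩ᵢ) / (Σnᵢ Σnᵢτᵢ² − (Σnᵢτᵢ)²).

   A track is called **mobile** when D_app exceeds 0.0003 µm²/s in at least
   10% of its segments; movies report percent mobile.

2. **Are they patterned?** 3D punctum coordinates per cell are centered,
   rotated onto the long axis (SVD of the scatter matrix), recentered at the
   midpoint using the hand-picked cell ends, fitted with a cylinder
   (least-squares circle in the Y/Z projection) and unrolled into a flat
   rectangle that is periodic around the circumference. On that surface the
   Clark–Evans ratio

   R = NNMD / (1 / (2√ρ)),   ρ = n / (2πrL),

   compares the observed nearest-neighbour mean distance with the Poisson
   expectation: R ≈ 1 for random placement, → 0 for clumping, and up to
   2√(2/√3) ≈ 2.149 for a triangular (grid-like) lattice. Each cell is
   compared against its own Monte-Carlo null — 1,000 simulated cells with the
   same punctum count, length and radius distribution, with a 100 nm
   minimum-separation cutoff emulating the imaging resolution floor — via an
   empirical CDF probability, and strains are tested with a paired two-sided
   t-test of observed R against per-cell null means.

3. **Do their subunits exchange?** FRAP intensity series for bleached
   (targeted), same-cell untargeted and separate-cell untargeted puncta are
   background-corrected and expressed as percent of pre-bleach fluorescence;
   a static complex stays flat after bleaching while an exchanging pool
   recovers at the expense of its same-cell neighbours.

Every stage ships with a synthetic-data generator (Brownian tracks rendered
as noisy movies; random / grid / clumped puncta on jittered cylinders; FRAP
series under static and exchange kinetics) so the full pipeline is testable
against known ground truth without any microscopy data.

## Worked example

```r
library(punctadyn)

## mobility: 8 puncta, one truly diffusing at D = 0.003 um^2/s
tracks <- simulate_tracks(n_particles = 8, n_frames = 240,
                          d = c(0.003, rep(0, 7)), sigma_loc = 0.02,
                          dt = 0.25,
                          origin_x = rep(c(1.3, 3.2, 5.1), times = 3)[1:8],
                          origin_y = rep(c(1.3, 3.2, 5.1), each = 3)[1:8],
                          seed = 1)
movie  <- render_movie(tracks, nrow = 64, ncol = 64, pixel_size_um = 0.1,
                       seed = 2)
linked <- track_movie(movie)
summarize_movie(linked, dt = 0.25)
#> movie_summary movie_1: 8/14 tracks scored (6 too short), 1 mobile (12.5%)

## patterning: one random cell against its randomization null
cell <- simulate_cell_puncta("random", n_puncta = 25, length_um = 4,
                             radius_mean_um = 0.4, cutoff_um = 0.1, seed = 3)
res <- analyze_cell(cell, n_sims = 1000, cutoff_um = 0.1, seed = 4)
#> n = 25 puncta, CE = 1.081, null mean = 1.090 (sd 0.104), ECDF p = 0.93

## FRAP: exchanging pool recovers, same-cell puncta lose commensurately
frap <- simulate_frap("exchange", k = 0.15, noise_sd = 2, seed = 5)
summ <- percent_of_original(subtract_background(frap$data))
recovery_score(summ)
#>  same_cell separate_cell   targeted
#>  -43.67         0.55         41.48
```

The movie summary finds the 8 rendered puncta (six 1-frame noise tracks are
too short to score and are only counted), calls exactly the one truly
diffusing punctum mobile, and reports 1/8 = 12.5% mobile. The random cell's
Clark–Evans ratio (1.081) sits inside its own null (mean 1.090 — slightly
above 1 because of the 100 nm cutoff), so the ECDF probability is
unremarkable. The FRAP scores show targeted recovery mirrored by same-cell
loss, the signature of subunit exchange through a shared pool.

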