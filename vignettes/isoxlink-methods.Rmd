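---
title: "Methods: identifying transglutaminase isopeptide cross-links from MS2 spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying transglutaminase isopeptide cross-links from MS2 spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoxlink)
```

## The problem

Transglutaminases (TGs) condense the side-chain amide of a glutamine with
the epsilon-amine of a lysine, forming an
N&epsilon;(&gamma;-glutamyl)lysine isopeptide bond and releasing one
ammonia. After protease digestion of a cross-linked protein, the two
peptides around the bond stay covalently joined, producing a *branched*
peptide pair that standard linear-peptide search engines cannot identify.
`isoxlink` is a search engine for exactly this product class: it takes
protein sequences (FASTA) and MS2 peak lists (MGF), and reports which
(Q position, K position) pairs in the target protein are supported by the
fragmentation data.

## Mass model

All arithmetic is monoisotopic. A peptide's neutral mass is the sum of its
residue masses plus one water plus any modification deltas. The
cross-linked pair's neutral mass is

$$M_\text{pair} = M_\alpha + M_\beta - M_{\mathrm{NH_3}},$$

with $M_{\mathrm{NH_3}} = 17.026549$ Da. Ions are charged by proton
addition, $m/z = (M + z \cdot 1.007276)/z$. Note that the cross-link delta
is an **ammonia** loss, not a hydroxyl loss, although the two round to the
same $-17.03$ Da at 2 dp: the condensation of an amide with an amine
releases NH~3~, and only the ammonia value reproduces the model pair's
printed precursor masses from its chain masses.

```{r}
pair <- crosslinked_pair("EGGKGPR", "SQDGGR", k_pos = 4, q_pos = 2)
pair_mass(pair)          # 1300.612
mz(pair_mass(pair), 2:4) # 651.31, 434.54, 326.16
```

## Digestion and candidates

Digestion is fully specific trypsin (cleave after K/R, suppressed before
P, both configurable) with missed cleavages and 6--40 residue length
bounds. Sequential Lys-C + trypsin protocols are modeled as plain trypsin,
whose cleavage set contains Lys-C's. Decoys are whole-protein sequence
reversals, digested identically.

A cross-linkable lysine must be internal (the cross-link blocks cleavage
at its own position, so an observed cross-linked peptide carries its K
internally), and consequently that missed cleavage must not count against
the missed-cleavage budget: the pipeline digests with one extra allowed
missed cleavage and discounts the cross-linked K site during pair
enumeration. A deamidated glutamine is not cross-linkable, since
deamidation consumes the same side-chain amide.

Fixed modifications (carbamidomethyl-C) are always applied; variable
modifications (oxidation-M, deamidation-Q) are expanded combinatorially up
to a per-peptide cap (default 2). Candidate pairs are all (K-donor,
Q-donor, site) combinations whose pair mass is within the precursor
tolerance (default &plusmn;20 ppm).

## Fragmentation

Ion-trap CID produces predominantly b/y ions, so only those series are
generated (an extension hook for other series is deliberately absent). For
each chain of length $n$: $b_1..b_{n-1}$ and $y_1..y_{n-1}$ at charges
$1..\min(z_\text{prec}-1, 3)$. A fragment whose span includes the
cross-linked site carries the *entire* partner chain as a fixed mass
addition ($M_\text{partner} - M_{\mathrm{NH_3}}$); fragments are never
cleaved inside the partner chain. This yields the conservation identity
used as a self-test: complementary $b_i + y_{n-i}$ of either chain sum to
$M_\text{pair}$ (in neutral-mass convention), since exactly one of the two
carries the partner.

## Scoring

The per-spectrum scores are documented surrogates: the originals used in
the reference workflow are proprietary and unpublished, so the printed
score values from that software (22, 10, 5.4--9.9) are treated as
qualitative anchors for ordering and thresholds, not as bit-targets.

* **score** (descriptive, 0--100): percentage of total ion intensity
  carried by matched peaks. Independent of peptide length.
* **pp**: $-\log_{10} P(X \ge k)$, $X \sim \text{Binomial}(n, p)$ over the
  $n$ theoretical fragments with $k$ matched, where
  $p = \min(1,\, n_\text{peaks} \cdot 2\,\text{tol}/W)$ is the chance of a
  single fragment hitting some peak at random in an acquisition window of
  width $W$ (default 150--2000 Da).
* **pp2**: abundance analogue of pp. Under the null, each peak is hit
  independently with probability
  $q = 1 - (1 - 2\,\text{tol}/W)^{n}$ and the null statistic is the
  intensity sum of hit peaks; pp2 is $-\log_{10}$ of the probability that
  this sum reaches the observed matched intensity. The tail is estimated
  by seeded Monte-Carlo (10,000 draws, +1 pseudocount). Because that
  estimator saturates at $-\log_{10}(1/10001) \approx 4$, which is *below*
  the conventional minimum of 5, the tail is extrapolated with the
  closed-form Gaussian approximation (mean $q\sum I_i$, variance
  $q(1-q)\sum I_i^2$) whenever no null draw reaches the observed value. An
  earlier candidate null --- a uniformly random subset of fixed size $k$
  --- was measured to be non-extreme even for perfect matches when $k$ is
  a large fraction of the peaks and intensities are heavy-tailed, and was
  rejected: it would have made the threshold pp2 &ge; 5 unattainable by
  any spectrum.
* **pp_tag**: sequence-tag score. With $L$ the longest run of consecutive
  matched indices within one (chain, series),
  $-\log_{10}\min(1, n_\text{pos} \cdot p^L)$; zero for $L \le 1$. Long
  uninterrupted ladders distinguish a genuine backbone series from
  scattered coincidences.

Peak assignment is deterministic: each theoretical fragment takes the most
intense peak within &plusmn;0.8 Da, ties broken by smaller absolute error,
then lower m/z.

## Site aggregation and the decision rule

Each spectrum is assigned to its single best-scoring candidate pair
(rank-1 assignment, targets and decoys competing). Without this rule,
near-equivalent explanations that share most fragments --- an alternative
K inside the same chain, or the role-swapped K/Q assignment when missed
cleavages put both residue types in both chains --- would also pass
thresholds, and no unique identification would ever be possible.

Per site, the **overall score** is the sum over spectra passing the
per-spectrum minima (pp &ge; 5, pp2 &ge; 5, pp_tag &ge; 1.3) of
mean(pp, pp2, pp_tag). A site is **accepted** iff overall &ge; 15 *and* it
has &ge; 2 passing spectra; the spectral-count rule is a separate AND
condition because single-spectrum identifications proved unreliable across
collision energies in the motivating work. Decoy-containing (TD/DD) sites
are never flagged accepted --- they exist to calibrate error --- but they
drive the q-value estimate
$\mathrm{FDR}(t) = \max(0, \mathrm{TD}-\mathrm{DD})/\max(1, \mathrm{TT})$
over score thresholds $t$.

## The synthetic-spectrum generator

There is no desk-scale real dataset: the deposited raw data require a
proprietary scorer and large downloads. The generator therefore *is* the
test world, and its defaults state that world once:

| knob | default | meaning |
|---|---|---|
| `fragment_coverage` | 0.8 | fraction of theoretical fragments emitted; the collision-energy abstraction (over/under-fragmentation = low coverage) |
| `noise_peaks` | 30 | uniform random peaks over the window |
| `mz_jitter_sd` | 0.1 Da | ion-trap mass error; clipped at 0.75 Da so peaks stay inside the 0.8 Da matching tolerance |
| `intensity_meanlog`, `intensity_sdlog` | 10, 1 | log-normal signal intensities (heavy-tailed, like real ion counts) |
| noise intensity | lower quartile of the signal model | controllable but realistic signal-to-noise |
| `mz_range` | 150--2000 Da | acquisition window |

What a green test establishes: the pipeline recovers planted cross-links
under fragment incompleteness, mass jitter and uniform noise, and rejects
pure noise. What it does not establish: robustness to correlated
chemical noise (neutral losses, internal ions, co-isolated precursors),
isotope envelopes, or real intensity structure along ion series --- none of
which the generator emulates.

The `synthetic_collagen()` sequence is a **synthetic stand-in**, not the
real collagen alpha-1(I) entry: it places the model peptides EGGKGPR at
893--899 and SQDGGR at 1198--1203 so the K896/Q1199 coordinate bookkeeping
can be exercised offline.

## Numerical choices and degenerate inputs

* Display rounding is half-away-from-zero at 2 dp; full precision is kept
  internally.
* All `-log10` scores are capped at 300; the pp2 extrapolated tail is
  floored at $10^{-300}$.
* A spectrum with zero total intensity has no defined descriptive score
  (error); an empty peak list yields empty matches, score 0.
* Seeds: every stochastic step (generator, pp2 null) takes an explicit
  seed; per-spectrum seeds are derived as `(seed + 7919 * i) mod (2^31-1)`.
  Same inputs + seed give byte-identical outputs.
* Monte-Carlo draws for pp2 default to 10,000; raising them sharpens the
  estimate near the threshold but the Gaussian extrapolation governs the
  deep tail either way.

## Known limitations

* Only inter-peptide cross-links: no loop-links, mono-links, or chemical
  cross-linkers with spacer arms.
* Only b/y ions; HCD/ETD fragment types are out of scope.
* One cross-link per peptide pair.
* The FDR estimator is a plug-in over a usually small site list; with no
  decoy hits it reports 0 by construction, which mirrors the reference
  workflow's "0% FDR" output but should be read as "no measurable error",
  not "no error".
* mzML input is not implemented; MGF is the required carrier. Config files
  are JSON (a YAML reader is not part of the dependency budget).
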