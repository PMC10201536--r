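# tautopath

Desk-scale analysis of adenine–thymine tautomerization during DNA strand
separation.

When a helicase pulls the two strands of a DNA duplex apart, the A–T base
pair can undergo a stepwise double proton transfer: thymine first donates
the proton of hydrogen bond B2, forming the zwitterion A⁺–T⁻, and a second
transfer along B1 then yields the tautomeric pair A\*–T\*. A tautomer
trapped on a separating strand can mispair at the next replication, so
three quantities decide whether this is a credible mutation mechanism:

* the **onset separation** `d*` at which the tautomeric state first
  becomes a bound minimum of the landscape;
* the growth law of the **reverse barrier** `Er1(d) ∝ d^p` that protects
  the tautomer as separation continues (near-quadratic exponents `p`);
* the **minimum lifetime** `t = d_crit / v` the tautomer needs in order to
  be carried past the critical separation at the strand-separation speed
  `v`.

`tautopath` implements the full pipeline on top of two transparent model
systems: a calibrated two-coordinate energy surface `V(q1, q2; d)` for the
proton transfers (tilted-quartic steps, a sequential-mechanism switch, and
separation-dependent barrier laws), and a planar coarse-grained bead–spring
duplex with breakable Morse hydrogen bonds for steered Langevin unzipping.
The toolkit around them is general: constrained separation scans,
climbing-image elastic-band path search with string preconditioning, a
derivative-enhanced Gaussian-process surrogate accelerator with
uncertainty-controlled acquisition, stationary-point/barrier/stability
analytics, power-law fits, and replica-ensemble opening-angle and
separation-speed statistics. Everything is tibble-in/tibble-out with
`autoplot()` and broom-style `tidy()`/`glance()` methods.

## Worked example

```r
library(tautopath)

rep <- landscape_report(surface_params("AT"))
rep
#> <landscape_report> AT preset
#>   onset separation: 0.444 A
#>   reverse-barrier power law: exponent 1.8940 (R^2 1.00000)
#>   minimum tautomer lifetime: 1.600 ps
#>   temperature equivalent of largest reverse barrier: 2e+04 K

dplyr::select(rep$barriers, d, Ef1, Er1, Ef2, Er2, classification)
#>       d   Ef1   Er1    Ef2    Er2 classification
#> 1 0.000 0.650 0.100     NA     NA        unbound
#> 2 0.222 0.746 0.140     NA     NA        unbound
#> 3 0.444 0.911 0.256 0.0213 0.0705         stable
#> 4 0.666 1.141 0.427 0.1524 0.1823         stable
#> 5 0.888 1.431 0.663 0.2867 0.2936         stable
#> 6 1.110 1.780 0.958 0.4215 0.4048         stable
#> 7 1.332 2.188 1.307 0.5515 0.5159         stable
#> 8 1.554 2.652 1.724 0.6928 0.6269         stable
```

Each row is one imposed separation increment (0.222 Å spacing). `Ef1/Er1`
are the forward/reverse barriers of the first transfer (B2 proton,
canonical → zwitterion), `Ef2/Er2` those of the second (B1 proton,
zwitterion → tautomer), all in eV from converged climbing-image paths. At
0 and 0.222 Å the path profile has a single saddle — there is no
double-transfer minimum — while from the third increment (0.444 Å)
onwards a bound tautomeric well appears and deepens, which is exactly the
onset the report prints. The exponent is recovered from the
baseline-subtracted `Er1` series by a log–log least-squares fit; the
lifetime is `2.0 Å / 1.25 Å·ps⁻¹ = 1.6 ps`; the temperature equivalent
`Er1/k_B ≈ 2 × 10⁴ K` of the largest scanned reverse barrier is the
trapping argument — no biological temperature reverses the transfer once
the strands are well separated.

Other entry points: `run_separation_scan()` (bond stretching and opening
angle versus separation, canonical or tautomeric form), `mlneb_run()`
(surrogate-accelerated path search with an evaluation log),
`build_duplex()` + `run_steered()` + `angle_histogram()` +
`separation_speed()` (steered unzipping ensembles), and `run_pipeline()`
(command-style interface writing CSV/JSON artifacts with a manifest; a
thin shell wrapper lives in `inst/scripts/tautopath.R`). Presets `"AT"`
and `"GC"` ship as YAML under `inst/extdata/`.

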