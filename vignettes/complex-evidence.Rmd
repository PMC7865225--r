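---
title: "Complex evidence theory with cbelief: model, distances, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complex evidence theory with cbelief}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbelief)
```

## The model

A frame of discernment `Φ = {φ1, …, φn}` is a finite set of mutually
exclusive, exhaustive hypotheses. Classical Dempster–Shafer theory assigns
each non-empty subset `A ⊆ Φ` a real mass `m(A) ∈ [0,1]` with
`Σ m(A) = 1`. Complex evidence theory keeps the same combinatorial
structure but lets each mass be a complex number

$$M(A) = m(A)\,e^{i\theta(A)}, \qquad m(A) \in [0,1],\;
\theta(A) \in [-\pi,\pi], \qquad \sum_{A \subseteq \Phi} M(A) = 1 + 0i,$$

with `M(∅) = 0`. The magnitude is the degree of support for `A`; the phase
is a second degree of freedom that lets sources interfere constructively or
destructively when combined. A CBBA whose masses are all real and
non-negative is exactly a classical BBA, and every operation in this
package then reduces to its classical counterpart.

Assumptions inherited from the classical theory: the frame is closed-world
(no mass on `∅`, so evidence cannot support "none of the hypotheses"),
sources to be combined are independent, and subsets are compared by their
member sets only (the frame order is purely a storage convention).

`cbelief` stores masses in Cartesian form (`re`, `im`): every defining sum
— normalization, combination, pignistic transformation — is linear in the
Cartesian components, while polar form is only convenient for input and
display. `from_polar()` and `from_polar_tan()` convert on the way in;
subsets are keyed by a bitmask over the frame order.

## Fusion and conflict

The complex Dempster rule combines two CBBAs by accumulating mass products
on the intersections of their focal elements and renormalizing:

$$M(A_k) = \frac{1}{1-K} \sum_{A_i \cap A_h = A_k} M_u(A_i) M_v(A_h),
\qquad K = \sum_{A_i \cap A_h = \emptyset} M_u(A_i) M_v(A_h).$$

`K` is complex; its modulus `|K|` is the usual conflict measure, and for
complex masses it can exceed 1 (the highly conflicting pair in
`cet_example("ex1")` has `|K| = 1.0002`). Division by `1 − K` is full
complex division; the formula is evaluated as written whenever
`|1 − K| ≥ tol_k`, and refused as total conflict below that. `|K|` is also
an imperfect conflict measure — two identical uniform-singleton BBAs
(`cet_example("ex3")`) have `|K| = 0.75` despite agreeing completely —
which is what motivates a distance on betting commitments instead.

## Pignistic transformation and the BCD

The complex pignistic transformation splits each focal mass equally over
its members,

$$CPT(\varphi_j) = \sum_{A \ni \varphi_j} \frac{M(A)}{|A|}, \qquad
CPT(A) = \sum_{\varphi_j \in A} CPT(\varphi_j),$$

and the betting commitment is its modulus, `BetC(A) = |CPT(A)|`. The
distance between two CBBAs is the worst betting-commitment disagreement
over all non-empty subsets:

$$d_{BCD}(M_u, M_v) = \max_{\emptyset \neq A \subseteq \Phi}
\bigl|\,BetC_{M_u}(A) - BetC_{M_v}(A)\,\bigr|.$$

The max aggregator is deliberate: a min or mean washes out exactly the
strongly conflicting subsets the distance exists to expose, so no
alternative aggregator is offered.

Two design points deserve explanation:

- **Denominator choice.** One can also write a pignistic-style form that
  divides by the cardinality of the *queried* subset,
  `Σ M(A_i)|A_i ∩ A_h| / |A_h|`. That variant is not additive over
  singletons and does not reproduce the package's reference betting
  commitments or distances; the additive focal-cardinality form above is
  therefore the default, and the variant is kept behind
  `cpt(..., method = "target")` purely so users can audit the difference.
- **Pseudo-metric, not metric.** BCD is non-negative, symmetric, and
  satisfies the triangle inequality (each follows from the corresponding
  property of `|·|` and `max`), and `M_u = M_v` implies distance 0. The
  converse fails: `m1({a}) = m1({b}) = 0.5` and `m2({a,b}) = 1` have
  identical pignistic transforms, hence `bcd(m1, m2) = 0` with `m1 ≠ m2`.
  The package documents BCD as a pseudo-metric, pins this counterexample
  in the test suite, and never relies on strict nondegeneracy.

On classical inputs BCD coincides with Liu's difBetP. `difbetp()` computes
it in pure real arithmetic via a closed form: classical `BetP` is additive
over disjoint singletons, so the maximizing subset collects either all
positive or all negative singleton differences. `bcd()` itself never uses
this shortcut — moduli are not additive — and instead evaluates all
`2^n − 1` subsets through a doubling construction (append one element at a
time, doubling the vector of subset sums), costing `O(2^n)` complex
additions. The equality of the two routes on classical inputs is asserted
to `1e-12` in the tests, alongside a brute-force per-subset oracle.

## Multi-attribute classification

A sample `s` and patterns `p_j` each carry one CBBA per attribute
`a_1, …, a_η` over a shared frame. The per-attribute distances are
aggregated either uniformly or with weights `w_κ ≥ 0`, `Σ w_κ = 1`:

$$d(s, p_j) = \sum_{\kappa=1}^{\eta} w_\kappa\,
d_{BCD}\!\left(M_s^{a_\kappa}, M_{p_j}^{a_\kappa}\right),$$

and `classify_sample()` assigns `s` to the pattern with minimal distance.
Ties at the minimum are broken in favour of the earliest pattern in the
supplied order — the argmin itself is silent on ties — and the result
carries a `tie` flag plus the full distance table so the decision is
auditable. The bundled diagnosis task (`cet_example("application")`: three
patterns, three attributes, frame `{y, n}`) yields distances
0.2157/0.2337/0.1525 uniformly and 0.2065/0.2303/0.1551 with weights
(0.3, 0.35, 0.35); both schemes choose `p3`.

```{r}
app <- cet_example("application")
classify_sample(app$cbbas$sample, app$cbbas$patterns, app$cbbas$weights)
```

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `tol_norm` | `cbba()`, readers | `1e-9` | allowed modulus of `Σ M(A) − 1`. Dimensionless. Exact Cartesian input satisfies `1e-9`; input transcribed from 4-decimal polar tables carries rounding of order `1e-4` per entry, so `cbba_tol(paper_rounded = TRUE)` = `1e-3`. |
| `tol_k` | `combine_cbba()` | `1e-9` | total-conflict guard on `|1 − K|`; prevents numerical blow-up of the `1/(1−K)` normalization. |
| `cap` | `fod()` | 20 | frame-size cap; distance evaluation touches all `2^n − 1` subsets (`n = 20` means ~10^6 complex terms, still well under a second). |
| `imag_scale` | `random_cbba()` | 0.2 | half-width of the imaginary-part draw; 0 yields classical BBAs, 0.5 is the permitted maximum. |

## The random generator and what the tests show

`random_cbba()` draws `n_focal` distinct subsets, positive real parts
rescaled to sum to 1, and imaginary parts uniform in
`[−imag_scale, imag_scale]` recentred to sum to 0, rejection-sampling
until every magnitude is ≤ 1. It is seeded explicitly and restores the
session RNG state, so property tests are reproducible draw by draw.

The generator emulates the *structure* of evidential data — valid
normalized CBBAs of controlled focality and complexity — and nothing about
any particular sensor: real multisource evidence has correlated attributes,
systematically skewed phases, and far-from-uniform magnitudes. Passing
property tests therefore certify the algebra (metric axioms, reduction
laws, fusion laws) over the whole CBBA space, not classification accuracy
on any real diagnostic population; the reference examples certify specific
desk-scale values.

Problem sizes used by the test suite: property suites run on 3–4 element
frames (500 pairs and 500 triples for the metric axioms, 200 commutativity
and 100 associativity pairs/triples), the classical-limit checks on the
20-element parametric pair cover all 20 growing hypotheses, and the whole
suite completes in well under a minute on one CPU.

## Numerical notes and degenerate inputs

- Comparisons against 4-decimal reference values use absolute tolerance
  `5e-4`; internal dual-route checks use `1e-12` (and `1e-9` after a
  three-way combination).
- Zero-magnitude entries are legal input (tabulated evidence often prints
  them) and are preserved for display, but they are not focal: they never
  contribute to `K`, combination, or the pignistic transform.
- The empty set is representable only to assert its mass is zero; all
  quantifications ("all subsets") mean non-empty subsets. `BetC(∅)` would
  be identically 0 and can never attain the max in the distance.
- `combine_cbba()` on disjoint certain evidence (`K = 1`) errors rather
  than returning an arbitrary CBBA.
- Phases outside `(−π/2, π/2)` (negative real parts) are accepted —
  nothing in the definitions forbids them — but all bundled reference
  evidence has non-negative real parts, so that region is exercised only
  by the validity checks, not by reference values.

## Known limitations

- Open-world (unnormalized, `M(∅) ≠ 0`) belief functions, interval-valued
  and fuzzy extensions are out of scope.
- No alternative combination rules (Yager, PCR5, discounting) and no
  rejection threshold in the classifier: a sample is always assigned to
  some pattern, however distant.
- BCD's pseudo-metric gap means pignistically equivalent evidence is
  indistinguishable to the classifier even when the underlying CBBAs
  differ.
- The frame cap of 20 is a practical bound for the exhaustive subset max;
  larger frames would need a different (approximate) distance.
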