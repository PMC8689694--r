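---
title: "Modeling ribosomal traffic in a whole cell: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ribosomal traffic in a whole cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotraffic)
```

## The model

`ribotraffic` simulates translation in a whole cell as a system of coupled
exclusion processes sharing one resource. The ingredients, per mRNA copy:

* a codon sequence of length $L$ with a per-codon translation delay
  $d(k) \ge 1$ (ticks);
* an initiation delay $t_{init}$ — the time a granted ribosome spends
  attaching at the 5' end before elongating;
* a diffusion delay $t_{diff}$ — the time a terminated ribosome spends off
  the transcript before it rejoins the shared pool;
* a footprint $D$ (codons): consecutive ribosomes on one mRNA keep a
  positional gap of at least $D$.

Cell-wide, $R$ ribosomes circulate among $M$ mRNA copies. An mRNA *requests*
a ribosome when it is empty or when its youngest ribosome has cleared the 5'
footprint; a global arbiter decides which requesting mRNA receives each free
ribosome. A protein is counted at the completion of the final codon
(termination), before diffusion. The model is deterministic given the grant
decisions: codon delays are averages, not samples (randomized per-event
delays are a known extension we deliberately exclude, as are operon
reinitiation and mRNA/ribosome degradation).

### Time base

All delays and event times are non-negative integers in ticks of
$\Delta T$ seconds (default 1 ms, the scale at which one hardware clock
cycle retires one timer decrement in the bacterial setting). Real-unit
inputs should be quantized with round-half-up on load. Rates are reported
in proteins per second using $\Delta T$.

## Two engines, one semantics

### Time-event vectors

The event-driven engine computes, for each granted ribosome, the absolute
completion time of every step from just two inputs: the mRNA's delays and
the previous ribosome's vector. With $t(0) = t_{grant} + t_{init}$,

$$t(k) = \max\big(t(k-1),\; t_{prev}(k+D)\big) + d(k), \qquad k + D \le L,$$

and no blocking term for the last $D$ codons ($k + D > L$). The $\max$ is
the footprint exclusion: codon $k$ cannot start until the ribosome ahead
has completed codon $k+D$. Each of the $L$ delays is consumed exactly once
(codon 1 follows initiation). Release happens at $t(L) + t_{diff}$.

Two indexing conventions are fixed once: codon positions are 1-based in
every user-facing interface, and the *gate* — the time from which the mRNA
may request its next ribosome — is the completion of codon
$\min(D+1, L)$, which is exactly the instant the blocking term for a new
ribosome's first codon vanishes. The first ribosome of every mRNA is
requested at tick 0; we gate requests on footprint clearance only (the
granted ribosome then pays its own initiation delay), the one place where
the scheduling discipline admits more than one reading.

### The global scheduler

The event loop: absorb all releases due at the current time into the pool;
if no ribosome is free, jump to the earliest pending release; collect
requests; if nobody requests now, jump to the earliest request time; let
the arbitration policy grant free ribosomes to requesting mRNAs; recompute
the recipients' time-event vectors; repeat until the horizon. Ties within
a tick are broken by processing releases before requests, so a ribosome
freed at $t$ can be re-granted at $t$; among equal-time requests the policy
decides. Protein events at or before the horizon are counted.

The recorded iteration trajectory samples scheduler wake-ups only, so the
result also carries an exact free-pool step function (`pool`) rebuilt from
the grant and release event times; the optimizer's objective integrates
that step function, not the coarser iteration samples.

### The fixed-step oracle

`run_fixed_step_oracle()` re-implements the same semantics with none of
the event machinery: per-tick countdown timers, explicit ribosome queues,
movement processed 3'-to-5' so a chain of completions cascades within one
tick exactly as the $\max$-recursion implies. It exists (a) as an
independent correctness oracle — both engines must produce identical
protein counts and protein event times under deterministic policies and
under stochastic policies with a shared decision stream, which holds
because both engines invoke the policy at exactly the instants where
requesters and free ribosomes coexist — and (b) to host the hardware
cycle-mode arbiter semantics, which is tick-based by nature. It also
audits the positional gap between co-resident ribosomes at every tick
(`min_gap`), which never falls below $D$.

## Arbitration

The round-robin arbiter scans mRNA indices cyclically from a pointer and
is deterministic. Its bias: when most mRNAs can accept a ribosome (low and
intermediate $R$), a ribosome released by mRNA $i$ tends to be collected
by mRNA $i+1$. `neighbor_bias()` measures the successor-grant fraction —
1.0 for round-robin in the all-free regime versus $1/M$ for an unbiased
policy — and the bias shrinks as the cell saturates and fewer mRNAs are
free to receive.

The uniform arbiter replaces the scan counter with a random index draw.
Two modes exist because hardware and event scheduling count time
differently: in `event` mode (the event-driven engine) each grant is drawn
uniformly among current requesters without replacement; in `cycle` mode
(the oracle and the planner) one index is drawn per clock cycle regardless
of the indexed mRNA's state, and a miss grants nothing that cycle. The
draw-and-retry loss is harmless at full clock speed, which is why the two
modes allocate identically in distribution.

Counter sizing: a pending-release counter per mRNA must survive the
arbiter's revisit window $W$ without overflowing. For round-robin
$W = m$ exactly (one scan); for the uniform arbiter $W$ is the smallest
number of Bernoulli($1/m$) draws giving at least two successes with miss
probability below $p_{error}$, computed by exact binomial tails
(`bernoulli_window()`; $m = 2, p_{error} = 0.5$ gives $W = 4$). Successive
terminations on one mRNA are at least $D \cdot d_{minimal}$ ticks apart,
so the counter needs
$\lceil \log_2(\lfloor W/(D\,d_{minimal})\rfloor + 2) \rceil$ bits. The
closed form for the maximal release count is our interpretation of the
sizing argument; it is exposed as plain arithmetic so a different bound
can be substituted.

## The GF(2) generator

The uniform arbiter needs a compact hardware random source. The
construction: an $n$-bit state advanced by a binary matrix,
$x_{i+1} = A x_i$ over GF(2), with $A$ chosen by rejection so that (1)
each row has 4-6 ones — one 6-input LUT per state bit; (2) no column is
all zero — every state bit influences the next state; (3) the recurrence
is *full-cycle*: it visits all $2^n - 1$ nonzero states, i.e. the order of
$A$ is $2^n - 1$. Verification is by exhaustive orbit enumeration for
$n \le 20$ (bit-packed states and a parity table make the 65,535-step walk
fast) and by the order test
$A^{2^n-1} = I,\; A^{(2^n-1)/p} \ne I\ \forall p \mid 2^n-1$ in general;
the two verifiers agree wherever both run, and the search loop uses the
order test for speed. Dense rows are infeasible at small widths — no
full-cycle $4\times4$ matrix has rows of weight 3 or more — so below
$n = 8$ the default row-weight range relaxes to $[1, \min(6, n)]$.

The composite generator concatenates two 16-bit halves: the fast half
advances every step, the slow half once per $2^{16}-1$ steps (a 16-bit
wrap counter), extending the period to $(2^{16}-1)^2$; which half is fast
is an arbitrary fixed convention with no effect on the period structure.
The output is a projection $o_i = B x_i$ with $B$ a $9\times32$ matrix
(9 bits index up to 512 endpoints). $B$ must have full row rank to be
surjective onto the output space — and, because the slow half freezes for
a whole epoch, we additionally require full row rank on *each* 16-column
half-block of $B$; otherwise outputs within an epoch are confined to a
proper coset and fail uniformity badly. Index reduction to $[1, M]$ uses
rejection sampling rather than truncation, for exact uniformity. Over
moderate windows the full-cycle structure makes index counts *more* even
than iid draws, so the χ² uniformity statistic sits near the low tail —
the intended behaviour for an arbiter, not an anomaly. The construction
targets statistical uniformity only; it is nowhere near cryptographic.

## FGM/BGM silent-mutation optimization

The objective is the burn-in-trimmed time-average of the free ribosomal
pool (default burn-in: the first 20% of the horizon), under the constraint
that every mRNA's protein production rate stays within a symmetric
relative band of its own pre-optimization baseline
($|r - r_0| \le \theta\, r_0$, $\theta$ = 0.01-0.05 typically). The
mutable region defaults to codons 11-50, sparing the initiation-proximal
head. At each position the candidate replacement is the synonymous codon
with the smallest table delay, kept only if strictly faster — the choice
of synonym is otherwise unconstrained by the procedure's definition, and
the fastest one most directly relieves traffic.

The greedy loop (forward scan for FGM, backward for BGM): each mRNA's next
candidate position is tentatively applied and evaluated; the best-gaining
admissible mutation is committed; candidates that fail admissibility or
give no gain in their evaluation context are discarded and not revisited;
the loop stops when no mRNA offers a strictly positive admissible gain.
One committed mutation per iteration keeps FGM and BGM granularities
comparable (whether the original procedure commits one mutation or one
mRNA's whole scan per step is not recoverable; this is our choice). All
candidate evaluations share one seed (common random numbers), so
comparisons are paired even under stochastic arbitration. The committed
objective is non-decreasing by construction, and re-running the optimizer
on its own output commits nothing.

One property worth stating precisely: shortening a codon delay *behind*
the 5' gate (positions $> D+1$) can only shorten ribosome holding times
and thus never shrinks the mean free pool of a single-mRNA cell; but
shortening a delay at or before the gate codon also accelerates request
generation and can legitimately *drain* the pool. The greedy loop needs no
special handling — such mutations simply evaluate to negative gain — but
it is the reason the per-position gain is measured by simulation rather
than predicted from the delay change.

On toy cells small enough to enumerate every admissible mutation subset,
the greedy gain reaches the exhaustive optimum; in general greedy is a
heuristic and no optimality is claimed.

## Hardware planning abstractions

These are arithmetic models, not synthesis estimates:

* speed factor $\Delta T \cdot f$ and parallel runtime
  $(T_{sim}/\Delta T)/f$, independent of $R$ and $M$;
* per-mRNA ribosome-buffer allocation: `max` ($\lfloor L/D\rfloor + 1$,
  never saturates), `truncated` ($2\lceil R/M\rceil$, capped by the
  bound), and `weighted` — proportional to
  $w_i = \log(1 + L_i \bar d_i / (init_i + D \bar d_i))$, a log-smoothed
  combination of the three stated drivers of occupancy (length, codon
  time, entry time). The printed form of the original weight function is
  not recoverable, so this implementation is labelled an interpretation
  and is replaceable by any user weight function; its directional
  behaviour (longer/slower/faster-entering mRNAs get more slots) is
  tested, and on heterogeneous synthetic cells it saturates no more mRNAs
  than the truncated scheme;
* ROM accounting: a position-to-delay ROM costs
  $NDbits \cdot 2^{\lceil\log_2 L\rceil}$ bits; splitting it into a 6-bit
  position-to-code ROM plus one shared 64-entry code-to-delay table
  reduces the per-mRNA component by $NDbits/6$ (2.5× at the 15-bit delay
  width); the table's $64 \cdot NDbits$ bits are accounted separately as
  "table bits" — an abstract stand-in for a LUT-based table, since
  physical LUT/FF counts are out of scope;
* iterative-model timing: each global iteration costs the busiest mRNA's
  active-ribosome count plus a small constant overhead (default 2 cycles;
  no canonical figure exists), averaged over iterations.

## The synthetic-cell generator

`generate_cell()` draws one shared 61-entry sense-codon delay table per
run (as a hardware code-to-delay table would be), then per species a
length, a uniform-sense-codon sequence, an initiation delay and a copy
number. Defaults — lengths lognormal with median 300 codons, delays
uniform on 5-30 ticks, initiation 50-500 ticks, diffusion 10 ticks, 1 ms
ticks — are chosen once to produce non-degenerate traffic at desk scale
while keeping the bacterial proportions; the `ecoli_scale_config()` preset
moves to the published regime (512 species, tens of thousands of
ribosomes, $R$:mRNA ratio as in a bacterial cell). Stop codons, when
present, carry the fixed 1-tick terminating-position delay.
`replicate_by_abundance()` apportions a copy budget by largest remainder
with lexicographic tie-breaks.

What the generator does **not** emulate: codon usage bias, delay
distributions fitted to ribosome profiling, correlated initiation
strengths and abundances, UTRs and operon structure. Tests passing on
synthetic cells therefore establish the *mechanics* (conservation,
exclusion, engine equivalence, policy distributions, monotonicities) — not
quantitative agreement with any organism. Hooks for measured tables exist
(`read_delay_table()`, per-mRNA overrides, abundance replication), but
fitting them is outside this package.

## Numerical choices and degenerate inputs

* All delays are integers $\ge 1$; a zero delay is rejected at
  construction (it would allow same-tick passes).
* $L \le D$ is legal: the mRNA holds one ribosome at a time and the gate
  becomes termination.
* $R = 0$ is legal and produces zero proteins and zero grants.
* Admissibility comparisons use a $10^{-12}$ slack against floating-point
  noise in otherwise-integer arithmetic; a baseline rate of zero forces
  exact rate preservation.
* Rejection budgets (matrix search 10,000 tries) fail loudly with
  diagnostics rather than degrading.

Test problem sizes were chosen for coverage per unit time: engine
equivalence runs 50 random cells with $M \le 16$, $R \le 64$, $L \le 60$
over 600-tick horizons in both engines and both policies; arbiter
uniformity uses 64 endpoints and $10^5$ grants; the full-cycle orbit walk
is exhaustive at $n = 16$; saturation shapes use horizons of 3,000 ticks
over six pool sizes.

## Known limitations

Deterministic per-codon delays (averages); no tRNA-pool competition; no
degradation or reinitiation; the weighted-allocation and release-counter
closed forms are documented interpretations; the greedy optimizers carry
no optimality guarantee beyond the enumerable toys; and the event-driven
engine's uniform arbitration is event-mode only — cycle-mode experiments
belong to the tick-based oracle.
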