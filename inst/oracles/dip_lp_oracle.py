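#!/usr/bin/env python
"""Brute-force oracle for Hartigan's dip statistic.

The dip of an empirical CDF F_n is half the minimal sup-norm distance to a
unimodal CDF.  Any unimodal CDF can be replaced, without changing its values
at the data points, by one whose mode sits AT a data point (steepen the
rise inside the modal gap), so the exact dip is the minimum over all
candidate modal points t of a small linear programme:

    minimise eps over (v_1..v_m, eps) subject to
      b_j - eps <= v_j <= a_j + eps      (CDF corner bands at distinct x_j)
      0 <= v_j <= 1,  v nondecreasing
      slopes nondecreasing left of t (convex), nonincreasing right (concave)

where a_j / b_j are the lower/upper CDF corners after collapsing ties.
Solved with scipy's HiGHS LP solver; this is deliberately independent of
the modal-interval iteration used by the package.

Usage: dip_lp_oracle.py IN.json OUT.json
  IN.json : {"samples": [[...], [...], ...]}
  OUT.json: [dip1, dip2, ...]
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def dip_lp(sample):
    x = np.sort(np.asarray(sample, dtype=float))
    n = len(x)
    xd, first = np.unique(x, return_index=True)
    m = len(xd)
    if m == 1:
        return 0.0
    counts = np.diff(np.append(first, n))
    hi = np.cumsum(counts) / n          # upper corners b_j
    lo = hi - counts / n                # lower corners a_j

    best = np.inf
    for t in range(m):
        # variables: v_0..v_{m-1}, eps
        rows, rhs = [], []

        def add(coefs, b):
            r = np.zeros(m + 1)
            for idx, c in coefs:
                r[idx] = c
            rows.append(r)
            rhs.append(b)

        for j in range(m):
            add([(j, 1.0), (m, -1.0)], lo[j])       # v_j - eps <= a_j
            add([(j, -1.0), (m, -1.0)], -hi[j])     # -v_j - eps <= -b_j
        for j in range(m - 1):
            add([(j, 1.0), (j + 1, -1.0)], 0.0)     # monotone
        dx = np.diff(xd)
        for j in range(1, m - 1):
            c_prev = 1.0 / dx[j - 1]
            c_next = 1.0 / dx[j]
            if j < t:    # convex: s_{j-1} <= s_j
                add([(j - 1, -c_prev), (j, c_prev + c_next), (j + 1, -c_next)], 0.0)
            elif j > t:  # concave: s_{j-1} >= s_j
                add([(j - 1, c_prev), (j, -c_prev - c_next), (j + 1, c_next)], 0.0)

        c = np.zeros(m + 1)
        c[m] = 1.0
        bounds = [(0.0, 1.0)] * m + [(0.0, None)]
        res = linprog(c, A_ub=np.array(rows), b_ub=np.array(rhs),
                      bounds=bounds, method="highs")
        if res.status == 0 and res.fun < best:
            best = res.fun
    return float(best)


def main():
    with open(sys.argv[1]) as fh:
        payload = json.load(fh)
    dips = [dip_lp(s) for s in payload["samples"]]
    with open(sys.argv[2], "w") as fh:
        json.dump(dips, fh)


if __name__ == "__main__":
    main()
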