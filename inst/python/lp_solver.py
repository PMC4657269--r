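#!/usr/bin/env python
"""Generic sparse LP batch solver (HiGHS via scipy.optimize.linprog).

Reads a JSON file with a list of LP problems in sparse-triplet form and
writes a JSON list of solutions. Used as the numerical backend of the
rcfba R package; all model semantics live on the R side.

Input schema (per problem):
  n        : number of variables
  c        : objective coefficients (length n)
  sense    : "max" or "min"
  eq       : {"i": [...], "j": [...], "x": [...], "rhs": [...]}  (1-based rows/cols)
  ub       : same shape, rows are A x <= rhs
  lower    : variable lower bounds, null = -inf
  upper    : variable upper bounds, null = +inf
  c2       : optional second-stage objective (lexicographic): after stage 1,
             the stage-1 objective is fixed to within lex_tol of its optimum
             and c2 is optimized with sense2.
  sense2   : "max" or "min" (default "min")
  lex_tol  : absolute slack allowed on the stage-1 objective (default 1e-9)

Output (per problem):
  status      : "optimal" | "infeasible" | "unbounded" | "error"
  objective   : stage-1 optimal value (problem sense)
  objective2  : stage-2 value when requested
  x           : final solution vector
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import linprog

_STATUS = {0: "optimal", 1: "error", 2: "infeasible", 3: "unbounded", 4: "error"}


def _triplet_matrix(t, n):
    if t is None or len(t.get("rhs", [])) == 0:
        return None, None
    rhs = np.asarray(t["rhs"], dtype=float)
    i = np.asarray(t["i"], dtype=int) - 1
    j = np.asarray(t["j"], dtype=int) - 1
    x = np.asarray(t["x"], dtype=float)
    a = sparse.csr_matrix((x, (i, j)), shape=(len(rhs), n))
    return a, rhs


def _bounds(lower, upper, n):
    lo = [(-np.inf if v is None else float(v)) for v in lower] if lower else [0.0] * n
    hi = [(np.inf if v is None else float(v)) for v in upper] if upper else [np.inf] * n
    return list(zip(lo, hi))


def solve_one(p):
    n = int(p["n"])
    c = np.asarray(p["c"], dtype=float)
    sense = p.get("sense", "max")
    sgn = -1.0 if sense == "max" else 1.0
    a_eq, b_eq = _triplet_matrix(p.get("eq"), n)
    a_ub, b_ub = _triplet_matrix(p.get("ub"), n)
    bounds = _bounds(p.get("lower"), p.get("upper"), n)

    res = linprog(sgn * c, A_ub=a_ub, b_ub=b_ub, A_eq=a_eq, b_eq=b_eq,
                  bounds=bounds, method="highs")
    status = _STATUS.get(res.status, "error")
    out = {"status": status, "objective": None, "objective2": None, "x": None}
    if status != "optimal":
        return out
    obj1 = float(sgn * res.fun)
    out["objective"] = obj1
    out["x"] = [float(v) for v in res.x]

    if p.get("c2") is not None:
        c2 = np.asarray(p["c2"], dtype=float)
        sense2 = p.get("sense2", "min")
        sgn2 = -1.0 if sense2 == "max" else 1.0
        lex_tol = float(p.get("lex_tol", 1e-9))
        # pin stage-1 objective: c.x >= obj1 - tol (max) / c.x <= obj1 + tol (min)
        pin_a = sparse.csr_matrix(sgn * c.reshape(1, -1))
        pin_b = np.array([sgn * obj1 + lex_tol])
        if a_ub is not None:
            a_ub2 = sparse.vstack([a_ub, pin_a], format="csr")
            b_ub2 = np.concatenate([b_ub, pin_b])
        else:
            a_ub2, b_ub2 = pin_a, pin_b
        res2 = linprog(sgn2 * c2, A_ub=a_ub2, b_ub=b_ub2, A_eq=a_eq, b_eq=b_eq,
                       bounds=bounds, method="highs")
        if _STATUS.get(res2.status, "error") == "optimal":
            out["objective2"] = float(sgn2 * res2.fun)
            out["x"] = [float(v) for v in res2.x]
        # non-optimal stage 2 (numerical): keep stage-1 solution
    return out


def main(argv):
    if len(argv) != 3:
        sys.stderr.write("usage: lp_solver.py problems.json solutions.json\n")
        return 2
    with open(argv[1]) as fh:
        spec = json.load(fh)
    problems = spec["problems"] if isinstance(spec, dict) else spec
    sols = [solve_one(p) for p in problems]
    with open(argv[2], "w") as fh:
        json.dump(sols, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
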