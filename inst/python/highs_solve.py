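"""MILP runner: solves a model spec (JSON) with HiGHS via scipy.optimize.milp.

Usage: python highs_solve.py spec.json result.json
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp


def main(spec_path, out_path):
    with open(spec_path) as fh:
        spec = json.load(fh)
    ncol = int(spec["ncol"])
    nrow = int(spec["nrow"])
    c = np.asarray(spec["obj"], dtype=float)
    lb = np.asarray(spec["lb"], dtype=float)
    ub = np.asarray(spec["ub"], dtype=float)
    integrality = np.asarray(spec["integrality"], dtype=int)
    ai = np.asarray(spec["ai"], dtype=int) - 1
    aj = np.asarray(spec["aj"], dtype=int) - 1
    av = np.asarray(spec["av"], dtype=float)
    A = sparse.csc_array((av, (ai, aj)), shape=(nrow, ncol))
    clb = np.asarray([-np.inf if v is None else float(v) for v in spec["clb"]])
    cub = np.asarray([np.inf if v is None else float(v) for v in spec["cub"]])
    options = {"presolve": True}
    if spec.get("time_limit") is not None:
        options["time_limit"] = float(spec["time_limit"])
    if spec.get("mip_rel_gap") is not None:
        options["mip_rel_gap"] = float(spec["mip_rel_gap"])
    res = milp(
        c,
        constraints=LinearConstraint(A, clb, cub),
        integrality=integrality,
        bounds=Bounds(lb, ub),
        options=options,
    )
    out = {
        "status": int(res.status),
        "success": bool(res.success),
        "objective": None if res.x is None else float(res.fun),
        "mip_gap": None if getattr(res, "mip_gap", None) is None else float(res.mip_gap),
        "x": None if res.x is None else [float(v) for v in res.x],
    }
    with open(out_path, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
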