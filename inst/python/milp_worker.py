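"""MILP solve worker backed by scipy.optimize.milp (HiGHS).

Two modes:
  server            start a localhost socket server, print the port on stdout,
                    then answer one JSON request per line on a single
                    connection until EOF.
  oneshot IN OUT    read one JSON model from IN, write the result JSON to OUT.

Model JSON:
  {"c": [...], "integrality": [0/1,...], "lb": [...], "ub": [...],
   "A": {"i": [...], "j": [...], "v": [...], "nrow": R, "ncol": C},
   "cl": [...], "cu": [...], "time_limit": seconds or null}
Row/column indices are 0-based; bounds >= 1e29 in absolute value mean +/-inf.

Result JSON:
  {"status": "optimal"|"infeasible"|"time_limit"|"error",
   "objective": number or null, "x": [...] or null, "message": str}
"""
import json
import socket
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

INF = 1e29


def _definf(a):
    a = np.asarray(a, dtype=float)
    a = np.where(a >= INF, np.inf, a)
    a = np.where(a <= -INF, -np.inf, a)
    return a


def solve_one(model):
    try:
        c = np.asarray(model["c"], dtype=float)
        integrality = np.asarray(model["integrality"], dtype=int)
        lb = _definf(model["lb"])
        ub = _definf(model["ub"])
        a = model["A"]
        A = sparse.csc_matrix(
            (np.asarray(a["v"], dtype=float),
             (np.asarray(a["i"], dtype=int), np.asarray(a["j"], dtype=int))),
            shape=(int(a["nrow"]), int(a["ncol"])),
        )
        cl = _definf(model["cl"])
        cu = _definf(model["cu"])
        options = {"mip_rel_gap": 0.0}
        tl = model.get("time_limit")
        if tl is not None:
            options["time_limit"] = float(tl)
        res = milp(
            c,
            constraints=LinearConstraint(A, cl, cu),
            integrality=integrality,
            bounds=Bounds(lb, ub),
            options=options,
        )
        # scipy status codes: 0 optimal, 1 iteration/time limit, 2 infeasible,
        # 3 unbounded, 4 other
        if res.status == 0:
            return {
                "status": "optimal",
                "objective": float(res.fun),
                "x": [float(v) for v in res.x],
                "message": res.message,
            }
        if res.status == 2:
            return {"status": "infeasible", "objective": None, "x": None,
                    "message": res.message}
        if res.status == 1:
            return {"status": "time_limit", "objective": None, "x": None,
                    "message": res.message}
        return {"status": "error", "objective": None, "x": None,
                "message": res.message}
    except Exception as exc:  # surface as a status, never crash the worker
        return {"status": "error", "objective": None, "x": None,
                "message": repr(exc)}


def serve():
    srv = socket.socket(socket.AF_INET, socket.SOCK_STREAM)
    srv.bind(("127.0.0.1", 0))
    srv.listen(1)
    sys.stdout.write("%d\n" % srv.getsockname()[1])
    sys.stdout.flush()
    conn, _ = srv.accept()
    srv.close()
    f = conn.makefile("rw", encoding="utf-8", newline="\n")
    for line in f:
        line = line.strip()
        if not line or line == "QUIT":
            break
        result = solve_one(json.loads(line))
        f.write(json.dumps(result) + "\n")
        f.flush()
    conn.close()


def oneshot(path_in, path_out):
    with open(path_in) as fh:
        model = json.load(fh)
    result = solve_one(model)
    with open(path_out, "w") as fh:
        json.dump(result, fh)


if __name__ == "__main__":
    if len(sys.argv) >= 2 and sys.argv[1] == "server":
        serve()
    elif len(sys.argv) >= 4 and sys.argv[1] == "oneshot":
        oneshot(sys.argv[2], sys.argv[3])
    else:
        sys.stderr.write(__doc__)
        sys.exit(2)
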