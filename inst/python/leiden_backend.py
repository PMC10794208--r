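"""Leiden clustering backend with fixed members and node sizes.

Reads a job description (JSON) naming an edge file and a grid of
(sigma, resolution) combinations, runs constrained Leiden on each, and
writes one membership column per combination.

Job JSON schema:
  n_nodes        int
  edge_file      TSV with columns i, j, d2 (0-based node ids, squared L2)
  node_sizes     list[int]  (bp per node)
  fixed_nodes    list[int]  (0-based ids frozen in their singleton cluster)
  combos         list of {"sigma": float, "resolution": float}
  seed           int
  n_iterations   int (-1 = run to convergence)
  out_file       TSV: one row per node, one column per combo
"""

import json
import math
import sys

import igraph as ig
import leidenalg as la


def main(job_path):
    with open(job_path) as fh:
        job = json.load(fh)

    n = job["n_nodes"]
    srcs, dsts, d2s = [], [], []
    with open(job["edge_file"]) as fh:
        header = fh.readline()
        for line in fh:
            a, b, d2 = line.rstrip("\n").split("\t")
            srcs.append(int(a))
            dsts.append(int(b))
            d2s.append(float(d2))

    g = ig.Graph(n=n, edges=list(zip(srcs, dsts)), directed=False)
    node_sizes = [int(s) for s in job["node_sizes"]]
    init = list(range(n))
    fixed = [False] * n
    for v in job["fixed_nodes"]:
        fixed[v] = True
    is_fixed = fixed if any(fixed) else None

    memberships = []
    for combo in job["combos"]:
        sigma = combo["sigma"]
        res = combo["resolution"]
        weights = [math.exp(-d2 / sigma) for d2 in d2s]
        part = la.RBERVertexPartition(
            g,
            initial_membership=list(init),
            weights=weights,
            node_sizes=node_sizes,
            resolution_parameter=res,
        )
        opt = la.Optimiser()
        opt.set_rng_seed(int(job["seed"]))
        n_iter = int(job.get("n_iterations", -1))
        if n_iter < 0:
            while opt.optimise_partition(part, n_iterations=1,
                                         is_membership_fixed=is_fixed) > 0:
                pass
        else:
            opt.optimise_partition(part, n_iterations=n_iter,
                                   is_membership_fixed=is_fixed)
        memberships.append(part.membership)

    with open(job["out_file"], "w") as fh:
        fh.write("\t".join("combo_%d" % i for i in range(len(memberships))) + "\n")
        for v in range(n):
            fh.write("\t".join(str(m[v]) for m in memberships) + "\n")


if __name__ == "__main__":
    main(sys.argv[1])
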