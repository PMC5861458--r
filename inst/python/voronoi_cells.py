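"""Voronoi cell volumes for a 3D point set.

Reads a headerless CSV of x,y,z (nm) from argv[1], writes argv[2] as CSV
with columns volume,bounded. Cells touching infinity (hull-adjacent) get
volume = inf and bounded = 0. Voronoi cells are convex, so the volume of a
bounded cell is the convex hull volume of its vertices.
"""
import sys

import numpy as np
from scipy.spatial import ConvexHull, Voronoi


def main(inp, out):
    pts = np.loadtxt(inp, delimiter=",", ndmin=2)
    if pts.shape[0] < 5:
        raise SystemExit("need at least 5 points for a 3D Voronoi diagram")
    v = Voronoi(pts)
    n = pts.shape[0]
    vol = np.full(n, np.inf)
    bounded = np.zeros(n, dtype=int)
    for i in range(n):
        reg = v.regions[v.point_region[i]]
        if len(reg) == 0 or -1 in reg:
            continue
        verts = v.vertices[reg]
        try:
            vol[i] = ConvexHull(verts).volume
            bounded[i] = 1
        except Exception:
            pass  # degenerate cell stays unbounded/infinite
    with open(out, "w") as fh:
        fh.write("volume,bounded\n")
        for i in range(n):
            v = vol[i] if np.isfinite(vol[i]) else -1.0  # -1 marks unbounded
            fh.write("%r,%d\n" % (float(v), bounded[i]))


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
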