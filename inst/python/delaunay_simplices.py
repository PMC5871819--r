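"""Delaunay triangulation helper (qhull via scipy).

Usage: python delaunay_simplices.py points.txt simplices.txt
Reads whitespace-separated point coordinates (one point per row, 1-3 columns),
writes the 1-based vertex indices of the top-dimensional Delaunay simplices.
For 1-dimensional input the 'triangulation' is the chain of consecutive
points in sorted order.
"""
import sys

import numpy as np

pts = np.loadtxt(sys.argv[1], ndmin=2)
if pts.shape[1] == 1:
    order = np.argsort(pts[:, 0], kind="stable")
    simplices = np.column_stack([order[:-1], order[1:]])
else:
    from scipy.spatial import Delaunay

    simplices = Delaunay(pts).simplices
np.savetxt(sys.argv[2], np.asarray(simplices) + 1, fmt="%d")
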