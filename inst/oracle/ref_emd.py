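"""Reference empirical mode decomposition used as an independent test oracle.

Self-contained NumPy/SciPy implementation (classical Huang sifting with
mirror boundary extension and natural cubic splines). It shares no code with
the package's R/C++ path; tests compare the two decompositions on random
signals.

Usage: python ref_emd.py <in.csv> <out.csv>
  in.csv  — one column, the signal
  out.csv — one column per IMF (residual excluded)
"""
import sys
import numpy as np
from scipy.interpolate import CubicSpline


def extrema(x):
    d = np.diff(x)
    s = np.sign(d)
    # carry zero slopes forward so plateaus resolve to their trailing edge
    for i in range(1, len(s)):
        if s[i] == 0:
            s[i] = s[i - 1]
    ds = np.diff(s)
    imax = np.where(ds < 0)[0] + 1
    imin = np.where(ds > 0)[0] + 1
    return imax, imin


def envelope(x, idx, n):
    m = len(idx)
    t = list(idx.astype(float))
    y = [x[i] for i in idx]
    nm = min(2, m)
    for k in range(nm):
        if idx[k] > 0:
            t.insert(0, -float(idx[k]))
            y.insert(0, x[idx[k]])
    # after insertion order fix: ensure ascending
    for k in range(nm):
        j = m - 1 - k
        if idx[j] < n - 1:
            t.append(2.0 * (n - 1) - idx[j])
            y.append(x[idx[j]])
    order = np.argsort(t)
    t = np.asarray(t)[order]
    y = np.asarray(y)[order]
    t, keep = np.unique(t, return_index=True)
    y = y[keep]
    if t[0] > 0:
        t = np.insert(t, 0, 0.0)
        y = np.insert(y, 0, x[0])
    if t[-1] < n - 1:
        t = np.append(t, float(n - 1))
        y = np.append(y, x[-1])
    cs = CubicSpline(t, y, bc_type="natural")
    return cs(np.arange(n))


def mean_env(x):
    n = len(x)
    imax, imin = extrema(x)
    if len(imax) < 2 or len(imin) < 2 or len(imax) + len(imin) < 4:
        return None
    return 0.5 * (envelope(x, imax, n) + envelope(x, imin, n))


def n_extrema_zc(x):
    imax, imin = extrema(x)
    nz = 0
    prev = 0.0
    for v in x:
        if v == 0.0:
            continue
        if prev != 0.0 and (prev > 0) != (v > 0):
            nz += 1
        prev = v
    return len(imax) + len(imin), nz


def emd(x, max_imfs=10, sd_threshold=0.2, max_sift=50):
    x = np.asarray(x, dtype=float)
    e0 = float(np.sum(x**2))
    res = x.copy()
    imfs = []
    while len(imfs) < max_imfs:
        if e0 > 0 and np.sum(res**2) < 1e-12 * e0:
            break
        h = res.copy()
        m = mean_env(h)
        if m is None:
            break
        for _ in range(max_sift):
            h1 = h - m
            sdc = float(np.sum(m**2)) / max(float(np.sum(h**2)), 1e-300)
            h = h1
            m = mean_env(h)
            if m is None:
                break
            ne, nz = n_extrema_zc(h)
            if sdc < sd_threshold and abs(ne - nz) <= 1:
                break
        imfs.append(h)
        res = res - h
    return imfs


def main():
    xin, xout = sys.argv[1], sys.argv[2]
    x = np.loadtxt(xin, ndmin=1)
    imfs = emd(x)
    if imfs:
        np.savetxt(xout, np.column_stack(imfs), delimiter=",")
    else:
        open(xout, "w").close()


if __name__ == "__main__":
    main()
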