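# Independent reference solver for the optimisation-based PID.
# Maximises H(Z|XY) over the set Q of joint distributions q(x,y,z) with the
# (X,Z) and (Y,Z) marginals of a base distribution, by Frank-Wolfe with the
# HiGHS LP solver as linear oracle and a bounded golden-section line search.
# Input (stdin, JSON): {"p": flat list, "shape": [nx, ny, nz],
#                       "iters": optional}
# Output (stdout, JSON): {"UX":..., "UY":..., "R":..., "S":..., "g":...}
import sys, json
import numpy as np
from scipy.optimize import linprog, minimize_scalar

spec = json.load(sys.stdin)
shape = tuple(spec["shape"])
base = np.array(spec["p"], dtype=float).reshape(shape, order="F")
iters = int(spec.get("iters", 4000))
nx, ny, nz = shape

mxz = base.sum(1)
myz = base.sum(0)

rows, vals = [], []
for x in range(nx):
    for z in range(nz):
        r = np.zeros(shape); r[x, :, z] = 1
        rows.append(r.ravel()); vals.append(mxz[x, z])
for y in range(ny):
    for z in range(nz):
        r = np.zeros(shape); r[:, y, z] = 1
        rows.append(r.ravel()); vals.append(myz[y, z])
A = np.array(rows); b = np.array(vals)

def g_of(q):
    q = np.maximum(q, 0)
    qxy = q.reshape(shape).sum(2)
    t1 = np.where(q > 1e-300, q * np.log2(q), 0).sum()
    t2 = np.where(qxy > 1e-300, qxy * np.log2(qxy), 0).sum()
    return t2 - t1          # H(XYZ) - H(XY)

def grad_of(q):
    qq = np.maximum(q.reshape(shape), 1e-30)
    qxy = np.maximum(qq.sum(2), 1e-30)
    return (-np.log2(qq) + np.log2(qxy)[:, :, None]).ravel()

# start from the IPF fit of the uniform tensor to the two marginals
q = np.ones(shape) / (nx * ny * nz)
for _ in range(5000):
    q *= (mxz / np.maximum(q.sum(1), 1e-300))[:, None, :]
    q *= (myz / np.maximum(q.sum(0), 1e-300))[None, :, :]
q = q.ravel()

g = g_of(q)
for it in range(iters):
    c = -grad_of(q)   # linprog minimises
    lp = linprog(c, A_eq=A, b_eq=b, bounds=[(0, 1)] * q.size,
                 method="highs")
    if not lp.success:
        break
    d = lp.x - q
    if np.abs(d).max() < 1e-15:
        break
    phi = lambda t: -g_of(q + t * d)
    ls = minimize_scalar(phi, bounds=(0.0, 1.0), method="bounded",
                         options={"xatol": 1e-14})
    t = ls.x if -ls.fun > g else 0.0
    if t <= 0:
        break
    q = np.maximum(q + t * d, 0)
    g_new = g_of(q)
    if g_new - g < 1e-12 and it > 50:
        g = max(g, g_new)
        break
    g = max(g, g_new)

def H(p):
    p = p[p > 1e-14]
    return -(p * np.log2(p)).sum()

qq = q.reshape(shape)
HX = H(qq.sum((1, 2))); HY = H(qq.sum((0, 2))); HZ = H(qq.sum((0, 1)))
HXY = H(qq.sum(2).ravel()); HXZ = H(qq.sum(1).ravel())
HYZ = H(qq.sum(0).ravel()); HXYZ = H(qq.ravel())
H0Z = H(base.sum((0, 1))); H0XY = H(base.sum(2).ravel()); H0XYZ = H(base.ravel())
res = {
    "UX": HXY + HYZ - HY - HXYZ,
    "UY": HXY + HXZ - HX - HXYZ,
    "R": HX + HY + HZ - HXY - HXZ - HYZ + HXYZ,
    "S": (H0XY + H0Z - H0XYZ) - (HXY + HZ - HXYZ),
    "g": g,
}
json.dump(res, sys.stdout)
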