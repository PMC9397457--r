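"""Generate closed-form sensitivity code for the JCS projection equations.

The three projected angles are quotients theta_i = f_i/g of polynomial /
square-root expressions in the seven independent pose parameters
(theta, kx, ky, e1x, e1y, e3x, e3z), after eliminating the unit-norm
constraints (kz, e1z, e3y main-direction components) and the floating axis
e2 = (e3 x e1)/||e3 x e1||.  This script differentiates f1..f3 and g once,
applies common-subexpression elimination and emits the frozen R evaluator
R/sensitivity-exact.R.  Run from the repository root:

    python data-raw/generate_sensitivities.py
"""

import sympy as sp
from sympy.printing.rcode import rcode

th, kx, ky, e1x, e1y, e3x, e3z = sp.symbols(
    "th kx ky e1x e1y e3x e3z", real=True, positive=False
)

kz = sp.sqrt(1 - kx**2 - ky**2)
e1z = sp.sqrt(1 - e1x**2 - e1y**2)
e3y = sp.sqrt(1 - e3x**2 - e3z**2)

k = sp.Matrix([kx, ky, kz])
e1 = sp.Matrix([e1x, e1y, e1z])
e3 = sp.Matrix([e3x, e3y, e3z])

c31 = e3.cross(e1)
e2 = c31 / sp.sqrt(c31.dot(c31))

g = (e1.cross(e2)).dot(e3)
f1 = th * (e2.cross(e3)).dot(k)
f2 = th * (e3.cross(e1)).dot(k)
f3 = th * (e1.cross(e2)).dot(k)

xs = [th, kx, ky, e1x, e1y, e3x, e3z]
base = [f1, f2, f3, g]
exprs = list(base)
for fexpr in base:
    exprs.extend(sp.diff(fexpr, x) for x in xs)

reps, reduced = sp.cse(exprs, optimizations="basic")

lines = []
lines.append("# Generated by data-raw/generate_sensitivities.py -- do not edit by hand.")
lines.append("# Closed-form f1..f3, g and their partials w.r.t.")
lines.append("# (th, kx, ky, e1x, e1y, e3x, e3z); th in radians.")
lines.append(".sens_eval <- function(th, kx, ky, e1x, e1y, e3x, e3z) {")
for sym, expr in reps:
    lines.append("  %s <- %s" % (sym, rcode(expr)))
out = [rcode(e) for e in reduced]
lines.append("  f <- c(%s, %s, %s)" % (out[0], out[1], out[2]))
lines.append("  g <- %s" % out[3])
df_rows = []
for i in range(3):
    row = out[4 + 7 * i : 4 + 7 * (i + 1)]
    df_rows.append(", ".join(row))
lines.append("  df <- matrix(c(")
lines.append("    %s," % df_rows[0])
lines.append("    %s," % df_rows[1])
lines.append("    %s" % df_rows[2])
lines.append("  ), nrow = 3L, byrow = TRUE)")
dg = out[4 + 21 : 4 + 28]
lines.append("  dg <- c(%s)" % ", ".join(dg))
lines.append("  list(f = f, g = g, df = df, dg = dg)")
lines.append("}")

with open("R/sensitivity-exact.R", "w") as fh:
    fh.write("\n".join(lines) + "\n")
print("wrote R/sensitivity-exact.R with %d cse temporaries" % len(reps))
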