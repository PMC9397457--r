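# Generated by data-raw/generate_sensitivities.py -- do not edit by hand.
# Closed-form f1..f3, g and their partials w.r.t.
# (th, kx, ky, e1x, e1y, e3x, e3z); th in radians.
.sens_eval <- function(th, kx, ky, e1x, e1y, e3x, e3z) {
  x0 <- e1x*e3z
  x1 <- e1x^2
  x2 <- e1y^2 + x1 - 1
  x3 <- -x2
  x4 <- sqrt(x3)
  x5 <- e3x*x4
  x6 <- x0 - x5
  x7 <- x6^2
  x8 <- e1y*e3x
  x9 <- e3x^2
  x10 <- e3z^2 + x9 - 1
  x11 <- sqrt(-x10)
  x12 <- e1x*x11
  x13 <- x12 - x8
  x14 <- e1y*e3z
  x15 <- x11*x4
  x16 <- x14 - x15
  x17 <- x13^2 + x16^2 + x7
  x18 <- x17^(-1.0/2.0)
  x19 <- e3z*x6
  x20 <- x11*x13
  x21 <- e3x*x13
  x22 <- e3z*x16
  x23 <- sqrt(-kx^2 - ky^2 + 1)
  x24 <- e3x*x6
  x25 <- x11*x16
  x26 <- x18*(kx*(x19 + x20) - ky*(x21 - x22) - x23*(x24 + x25))
  x27 <- kx*x16 - ky*x6 + x13*x23
  x28 <- e1y*x13
  x29 <- x4*x6
  x30 <- x28 + x29
  x31 <- e1x*x13
  x32 <- x16*x4 - x31
  x33 <- e1x*x6
  x34 <- e1y*x16
  x35 <- x33 + x34
  x36 <- x18*(-kx*x30 - ky*x32 + x23*x35)
  x37 <- -x13
  x38 <- -x16
  x39 <- x37^2 + x38^2 + x7
  x40 <- x39^(-1.0/2.0)
  x41 <- kx*x40
  x42 <- 1.0/x23
  x43 <- x11*x38
  x44 <- x42*(x24 - x43)
  x45 <- ky*x40
  x46 <- 1.0/x4
  x47 <- e1x*e3x
  x48 <- e3z + x46*x47
  x49 <- 1.0/x17
  x50 <- x48*x6
  x51 <- x12*x46
  x52 <- x49*(x16*x51 + x20 + x50)
  x53 <- e3x*x11
  x54 <- e1x*x46
  x55 <- th*x18
  x56 <- x46*x8
  x57 <- e3x*x37
  x58 <- x56*x6
  x59 <- e1y*x11
  x60 <- e3z + x46*x59
  x61 <- -x38*x60 + x57 + x58
  x62 <- x49*x61
  x63 <- x49*(x16*x60 - x21 + x58)
  x64 <- e1y*x46
  x65 <- 1.0/x11
  x66 <- e1y + x47*x65
  x67 <- e3z*x65
  x68 <- x5*x65
  x69 <- x13*x66 - x16*x68 + x29
  x70 <- x49*x69
  x71 <- -x12 + x8
  x72 <- e3z*x4
  x73 <- 1.0/x39
  x74 <- x38*x65
  x75 <- x73*(x29 - x37*x66 + x5*x74)
  x76 <- x11*x37
  x77 <- x23*x40
  x78 <- x0*x65
  x79 <- e1y + x65*x72
  x80 <- x33 + x37*x78 - x38*x79
  x81 <- x49*x80
  x82 <- kx*x18
  x83 <- e3x*x65
  x84 <- -x80
  x85 <- x73*x84
  x86 <- x13*x42
  x87 <- x35*x42
  x88 <- x16*x4
  x89 <- e1x*x37
  x90 <- x73*(x38*x51 - x50 + x76)
  x91 <- x38*x4
  x92 <- x38*x54 + x71 + x89*x90 - x90*x91
  x93 <- e1x*x48 + x12*x64 - x33*x52 - x34*x52 + x6
  x94 <- -e1y*x37*x90 + x29*x90 - x33*x46 + x4*x48 + x59
  x95 <- x28*x62 + x29*x62 + x6*x64 + x71
  x96 <- -x61
  x97 <- x73*x96
  x98 <- e1y*x38*x73*x96 - e1y*x60 - x16 - x33*x97 - x54*x8
  x99 <- x38*x64 + x4*x60 + x47 + x89*x97 - x91*x97
  x100 <- -e1y*x66 + x2 + x28*x70 + x29*x70
  x101 <- -e1x*x4
  x102 <- e1y*x68 + x101 + x33*x70 + x34*x70
  x103 <- x49*(-x13*x78 + x16*x79 + x33)
  x104 <- e1y*x78 + x101 + x103*x28 + x103*x29
  x105 <- e1y*x79 + x1 - x103*x33 - x103*x34
  x106 <- x1*x67 + x31*x81 + x4*x79 - x81*x88
  x107 <- x11*x40
  f <- c(th*x26, -th*x27, th*x36)
  g <- x18*(-e3x*x30 + e3z*x35 - x11*x32)
  df <- matrix(c(
    x26, th*(x18*x19 + x18*x20 + x41*x44), -th*(e3x*x13*x18 - x18*x22 - x44*x45), x55*(kx*(e3z*x48 - x10 - x19*x52 - x20*x52) + ky*(x0*x11*x46 + x21*x52 - x22*x52 - x53) - x23*(e3x*x48 - x10*x54 - x24*x52 - x25*x52)), x55*(-kx*(-e3z*x56 + x19*x62 + x20*x62 + x53) + ky*(e3z*x60 + x21*x63 - x22*x63 + x9) - x23*(x11*x60 - x24*x62 - x25*x62 + x64*x9)), -th*(-ky*x18*(e3x*x66 - x21*x70 + x22*x70 + x5*x67 + x71) + x41*(x11*x66 - x19*x75 - x57*x65 + x72 + x75*x76) + x77*(e3x*x74 + x24*x75 - x43*x75 + x6)), -th*(x45*(e3z*x38*x73*x84 - e3z*x79 - x0*x83 - x16 - x57*x85) + x77*(e3z*x74 + x11*x79 + x24*x85 - x43*x85 + x47) - x82*(x0 - x13*x67 - x19*x81 - x20*x81 - x5)),
    -x27, -th*(-kx*x86 + x14 - x15), -th*(-ky*x86 - x6), -th*(kx*x51 - ky*x48 + x11*x23), th*(e3x*x23 - kx*x60 + ky*x56), -th*(kx*x68 + ky*x4 - x23*x66), th*(e1x*ky - kx*x79 + x23*x78),
    x36, -x55*(kx*x87 + x30), -x55*(ky*x87 - x31 + x88), -th*(-x18*x23*x93 + x41*x94 + x45*x92), -th*(x45*x99 + x77*x98 - x82*x95), x55*(-kx*x100 - ky*(e1x*x66 + x16*x4*x49*x69 - x2*x83 - x31*x70) + x102*x23), x55*(kx*x104 - ky*x106 + x105*x23)
  ), nrow = 3L, byrow = TRUE)
  dg <- c(0, 0, 0, -e3x*x40*x94 + e3z*x18*x93 - x107*x92, e3x*x18*x95 - e3z*x40*x98 - x107*x99, -e3x*x100*x18 + e3x*x40*x65*(x89 - x91) + e3z*x102*x18 - x107*(e1x*x66 + x3*x83 + x75*x89 - x75*x91) - x18*x28 - x18*x29, x18*(e3x*x104 + e3z*x105 - x106*x11 + x32*x67 + x35))
  list(f = f, g = g, df = df, dg = dg)
}
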