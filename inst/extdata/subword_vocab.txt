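a
able
ai
al
an
ance
and
ar
at
ate
ay
b
c
ch
ck
d
dis
e
ea
ed
ee
en
ence
ent
er
es
est
f
ful
g
h
he
i
ible
ic
in
ing
ion
ir
is
ish
it
ive
j
k
l
less
ly
m
ment
n
nd
ness
o
on
oo
or
ou
ous
over
ow
oy
p
ph
pre
q
qu
r
re
s
sh
sion
t
ter
th
the
tion
u
un
under
v
w
wh
x
y
z
ά
έ
ή
ί
α
αι
ας
β
γ
δ
ε
ει
ες
ζ
η
ης
θ
ι
ια
ικ
κ
λ
μ
μα
ν
ντ
ξ
ο
ος
ου
π
ρ
ς
σ
στ
τ
τα
τζ
τσ
υ
φ
χ
ψ
ω
ων
ϊ
ϋ
ό
ύ
ώ
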