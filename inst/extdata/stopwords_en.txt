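a
an
the
and
or
but
if
then
than
that
this
these
those
there
here
is
am
are
was
were
be
been
being
do
does
did
doing
have
has
had
having
will
would
shall
should
can
could
may
might
must
i
me
my
mine
we
us
our
ours
you
your
yours
he
him
his
she
her
hers
it
its
they
them
their
theirs
what
which
who
whom
whose
when
where
why
how
not
no
nor
so
too
very
just
of
to
in
on
at
by
for
with
about
against
between
into
through
during
before
after
above
below
from
up
down
out
off
over
under
again
further
once
as
while
because
until
some
any
each
few
more
most
other
such
own
same
both
all
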