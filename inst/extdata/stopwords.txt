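a
an
the
i
me
my
we
our
you
your
he
him
his
she
her
it
its
they
them
their
this
that
these
those
am
is
are
was
were
be
been
being
have
has
had
do
does
did
will
would
shall
should
can
could
may
might
must
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
then
once
here
there
when
where
why
how
all
any
both
each
few
more
most
other
some
such
no
nor
not
only
own
same
so
than
too
very
and
but
if
or
because
as
until
while
please
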