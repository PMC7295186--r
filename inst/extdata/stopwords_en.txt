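a
about
above
after
again
against
all
also
among
an
and
any
are
as
at
be
because
been
before
being
below
between
both
but
by
can
cannot
could
did
do
does
doing
down
during
each
few
for
from
further
had
has
have
having
here
how
however
if
in
into
is
it
its
itself
may
might
more
most
much
must
no
nor
not
of
off
on
once
only
or
other
our
out
over
own
per
same
should
so
some
such
than
that
the
their
theirs
them
then
there
these
they
this
those
through
thus
to
too
under
until
up
upon
very
was
we
were
what
when
where
whether
which
while
who
whom
why
will
with
within
without
would
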