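και
κι
το
τα
του
των
τη
την
της
τον
ο
η
οι
ένα
ένας
μια
μία
να
δεν
μην
είναι
ήταν
θα
ότι
πως
που
πού
με
σε
για
από
προς
στο
στη
στην
στον
στα
στους
στις
αλλά
ή
αν
ως
σαν
μου
σου
μας
σας
τους
τις
εγώ
εσύ
αυτός
αυτή
αυτό
αυτοί
αυτές
αυτά
εκείνος
εκείνη
εκείνο
κάθε
όλο
όλα
όλοι
όλες
πολύ
πιο
τι
ποιος
ποια
ποιο
όταν
όπου
γιατί
επειδή
λοιπόν
τώρα
εδώ
εκεί
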